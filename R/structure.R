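## Dot-bracket parsing, rendering, base-pair distance, compatibility.
## Internally everything is 0-based; user-facing messages are 1-based.

.RNA_BASES <- c("A", "C", "G", "U")

## canonical pairs (incl. wobble)
.ALLOWED_PAIRS <- c("AU", "UA", "GC", "CG", "GU", "UG")

## --- sequence helpers --------------------------------------------------

## normalise an RNA sequence string: uppercase, T -> U (warning), validate
.seq_norm <- function(seq) {
    if (!is.character(seq) || length(seq) != 1L || is.na(seq))
        stop("sequence must be a single character string")
    s <- toupper(seq)
    if (grepl("T", s, fixed = TRUE)) {
        warning("'T' converted to 'U' in input sequence")
        s <- gsub("T", "U", s, fixed = TRUE)
    }
    bad <- regexpr("[^ACGU]", s)
    if (bad > 0L)
        stop(sprintf("invalid residue '%s' at position %d (need A/C/G/U)",
                     substr(s, bad, bad), bad))
    if (nchar(s) < 1L) stop("sequence must have length >= 1")
    s
}

.seq_to_int <- function(s) {
    match(strsplit(s, "", fixed = TRUE)[[1]], .RNA_BASES) - 1L
}

## --- partner-vector layer (internal) ----------------------------------

## 0-based partner vector: partner[i+1] = j if (i, j) paired, -1 otherwise
.db_to_partner <- function(text) {
    chars <- strsplit(text, "", fixed = TRUE)[[1]]
    bad <- which(!chars %in% c(".", "(", ")"))
    if (length(bad))
        stop(sprintf("illegal character '%s' at position %d in dot-bracket string",
                     chars[bad[1]], bad[1]))
    n <- length(chars)
    partner <- rep.int(-1L, n)
    open <- integer(0)
    for (k in seq_len(n)) {
        if (chars[k] == "(") open <- c(open, k)
        else if (chars[k] == ")") {
            if (length(open) == 0L)
                stop(sprintf("unbalanced brackets: unmatched ')' at position %d", k))
            i <- open[length(open)]
            open <- open[-length(open)]
            partner[i] <- k - 1L
            partner[k] <- i - 1L
        }
    }
    if (length(open))
        stop(sprintf("unbalanced brackets: unmatched '(' at position %d", open[1]))
    partner
}

.partner_to_db <- function(partner) {
    n <- length(partner)
    out <- rep.int(".", n)
    idx <- seq_len(n) - 1L
    out[partner > idx] <- "("
    out[partner >= 0L & partner < idx] <- ")"
    paste(out, collapse = "")
}

.partner_to_pairs <- function(partner) {
    idx <- seq_along(partner) - 1L
    i <- idx[partner > idx]
    cbind(i = i, j = partner[i + 1L])
}

.pairs_to_partner <- function(pairs, len) {
    partner <- rep.int(-1L, len)
    if (nrow(pairs)) {
        partner[pairs[, 1L] + 1L] <- as.integer(pairs[, 2L])
        partner[pairs[, 2L] + 1L] <- as.integer(pairs[, 1L])
    }
    partner
}

## symmetric difference of two pair sets given as partner vectors: every
## pair in exactly one set marks both its positions as disagreeing
.bp_dist_partner <- function(pa, pb) {
    (sum(pa >= 0L & pa != pb) + sum(pb >= 0L & pb != pa)) %/% 2L
}

## --- exported operations ----------------------------------------------

#' Parse a dot-bracket secondary structure
#'
#' Parses a Vienna-dialect dot-bracket string (`.`, `(`, `)`) into a
#' [PairTable-class].  Unbalanced brackets and illegal characters raise a
#' parse error naming the first offending (1-based) position; a hairpin
#' loop smaller than 3 unpaired bases raises a validation error.
#'
#' @param text dot-bracket string (surrounding whitespace is trimmed).
#' @return a [PairTable-class].
#' @examples
#' parseDotBracket("((...))")
#' @export
parseDotBracket <- function(text) {
    if (!is.character(text) || length(text) != 1L || is.na(text))
        stop("'text' must be a single character string")
    text <- trimws(text)
    if (nchar(text) < 1L) stop("empty structure string")
    partner <- .db_to_partner(text)
    new("PairTable", len = length(partner), pairs = .partner_to_pairs(partner))
}

#' Render a PairTable as a dot-bracket string
#'
#' Inverse of [parseDotBracket()]: `parseDotBracket(renderDotBracket(pt))`
#' reproduces `pt`.
#'
#' @param pt a [PairTable-class].
#' @return dot-bracket string.
#' @export
renderDotBracket <- function(pt) {
    stopifnot(is(pt, "PairTable"))
    .partner_to_db(.pairs_to_partner(pt@pairs, pt@len))
}

#' Base-pair distance between two structures
#'
#' Cardinality of the symmetric difference of the two base-pair sets.  The
#' structures must have equal length.  This is the fourth term of the design
#' objective.
#'
#' @param a,b [PairTable-class] objects (or dot-bracket strings).
#' @return non-negative integer.
#' @examples
#' bpDistance("((...))", "(.....)")  # 1
#' @export
bpDistance <- function(a, b) {
    if (is.character(a)) a <- parseDotBracket(a)
    if (is.character(b)) b <- parseDotBracket(b)
    stopifnot(is(a, "PairTable"), is(b, "PairTable"))
    if (a@len != b@len)
        stop(sprintf("length mismatch: %d vs %d", a@len, b@len))
    .bp_dist_partner(.pairs_to_partner(a@pairs, a@len),
                     .pairs_to_partner(b@pairs, b@len))
}

#' Can a sequence realise a structure?
#'
#' `TRUE` iff every pair `(i, j)` of the structure is one of the six
#' canonical pair types AU/UA/GC/CG/GU/UG in the sequence.
#'
#' @param seq RNA sequence string.
#' @param pt a [PairTable-class] (or dot-bracket string) of equal length.
#' @return logical.
#' @export
isCompatible <- function(seq, pt) {
    s <- .seq_norm(seq)
    if (is.character(pt)) pt <- parseDotBracket(pt)
    stopifnot(is(pt, "PairTable"))
    if (nchar(s) != pt@len)
        stop(sprintf("length mismatch: sequence %d vs structure %d",
                     nchar(s), pt@len))
    if (nrow(pt@pairs) == 0L) return(TRUE)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    all(paste0(ch[pt@pairs[, 1L] + 1L], ch[pt@pairs[, 2L] + 1L]) %in%
            .ALLOWED_PAIRS)
}

## --- methods ------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("bpLength", "PairTable", function(x) x@len)

#' @rdname accessors
#' @export
setMethod("basePairs", "PairTable", function(x) {
    p <- x@pairs
    p[order(p[, 1L]), , drop = FALSE]
})

#' @rdname accessors
#' @export
setMethod("dotBracket", "PairTable", function(x) renderDotBracket(x))

setMethod("show", "PairTable", function(object) {
    cat(sprintf("PairTable of length %d with %d base pairs\n  %s\n",
                object@len, nrow(object@pairs), renderDotBracket(object)))
})
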