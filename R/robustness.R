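## Mutational robustness (neutrality) of a sequence.

## all 3L single-point mutants, ordered by position then residue A<C<G<U
.enumerate_mutants <- function(chars) {
    L <- length(chars)
    out <- character(3L * L)
    n <- 0L
    for (pos in seq_len(L)) {
        orig <- chars[pos]
        for (b in .RNA_BASES) {
            if (b == orig) next
            m <- chars
            m[pos] <- b
            n <- n + 1L
            out[n] <- paste(m, collapse = "")
        }
    }
    out
}

## coordinated pair-type swaps: for each structure pair (i, j), the five
## alternative canonical pair types (positions ascending, types in the
## fixed order AU, UA, GC, CG, GU, UG minus the current one)
.enumerate_pair_swaps <- function(chars, pairs) {
    if (nrow(pairs) == 0L) return(character(0))
    out <- character(0)
    for (r in order(pairs[, 1L])) {
        i <- pairs[r, 1L] + 1L
        j <- pairs[r, 2L] + 1L
        cur <- paste0(chars[i], chars[j])
        for (ty in .ALLOWED_PAIRS) {
            if (ty == cur) next
            m <- chars
            m[i] <- substr(ty, 1L, 1L)
            m[j] <- substr(ty, 2L, 2L)
            out[length(out) + 1L] <- paste(m, collapse = "")
        }
    }
    out
}

## internal: numeric neutrality of a normalised sequence string; the toy
## backend folds all mutants in compiled code, other backends go through
## the generic (cached) fold path
.neutrality_raw <- function(seq, backend, cache = NULL) {
    if (backend == "toy") return(c_toy_neutrality(.seq_to_int(seq)))
    L <- nchar(seq)
    wt <- .fold_raw(seq, backend, cache)
    mutants <- .enumerate_mutants(strsplit(seq, "", fixed = TRUE)[[1]])
    sims <- vapply(mutants, function(m) {
        f <- .fold_raw(m, backend, cache)
        1 - .bp_dist_partner(wt$partner, f$partner) / L
    }, numeric(1), USE.NAMES = FALSE)
    mean(sims)
}

#' Neutrality (mutational robustness) of a sequence
#'
#' Folds the sequence and each of its `3 L` single-point mutants, and
#' averages the base-pair similarity `1 - d_bp(S0, Sm) / L` between the
#' wild-type structure `S0` and each mutant structure `Sm`.  The result is
#' a number in `[0, 1]`: 1 means every mutant preserves the structure
#' exactly.  All mutants are evaluated exhaustively (no sampling), so the
#' value is deterministic given the backend.
#'
#' @inheritParams foldSequence
#' @return a [NeutralityValue-class].
#' @examples
#' neutrality("GGGGAAAACCCC")
#' @export
neutrality <- function(seq, backend = c("toy", "vienna"), cache = NULL) {
    backend <- .backend_check(backend)
    s <- .seq_norm(seq)
    new("NeutralityValue", value = min(1, .neutrality_raw(s, backend, cache)),
        mutantsEvaluated = 3L * nchar(s))
}

#' @rdname accessors
#' @export
setMethod("neutralityScore", "NeutralityValue", function(x) x@value)

#' @rdname accessors
#' @export
setMethod("mutantsEvaluated", "NeutralityValue", function(x) x@mutantsEvaluated)

setMethod("show", "NeutralityValue", function(object) {
    cat(sprintf("Neutrality %.4f (%d mutants evaluated)\n",
                object@value, object@mutantsEvaluated))
})
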