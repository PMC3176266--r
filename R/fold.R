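## Pluggable minimum-free-energy folding backends.
##
## "toy"    -- hermetic dynamic programme with stacking bonuses (compiled);
##             deterministic, no external dependency, pseudo-kcal/mol.
## "vienna" -- RNAfold subprocess from the ViennaRNA package; the production
##             engine (Turner energies, kcal/mol).

.TOY_INFO <- "toy-nussinov/1.0, stack=-(sum of pair strengths GC:3 AU:2 GU:1), min-hairpin=3, no-lonely-pairs"

.backend_check <- function(backend) {
    backend <- match.arg(backend, c("toy", "vienna"))
    if (backend == "vienna" && Sys.which("RNAfold") == "")
        stop("folding backend 'vienna' unavailable: RNAfold not found on PATH; ",
             "install ViennaRNA or select backend = 'toy'")
    backend
}

#' Create a fold cache
#'
#' A per-run memoisation environment keyed by backend and sequence.
#' Neutrality evaluation refolds thousands of near-duplicate sequences, so
#' sharing a cache across calls speeds design runs up considerably.
#'
#' @return an environment usable as the `cache` argument of
#'   [foldSequence()], [neutrality()], [anneal()] and [designSequences()].
#' @export
newFoldCache <- function() new.env(parent = emptyenv())

## internal raw fold: list(partner = 0-based partner vector, dG = numeric)
.fold_raw <- function(seq, backend, cache = NULL) {
    key <- NULL
    if (!is.null(cache)) {
        key <- paste0(backend, ":", seq)
        hit <- cache[[key]]
        if (!is.null(hit)) return(hit)
    }
    res <- if (backend == "toy") {
        r <- c_toy_fold(.seq_to_int(seq))
        list(partner = r$partner, dG = r$energy)
    } else {
        .fold_vienna(seq)
    }
    if (!is.null(cache)) cache[[key]] <- res
    res
}

.fold_vienna <- function(seq) {
    out <- suppressWarnings(
        system2("RNAfold", c("--noPS"), input = seq, stdout = TRUE))
    line <- grep("^[.()]+\\s+\\(", out, value = TRUE)
    if (length(line) == 0L)
        stop("could not parse RNAfold output: ", paste(out, collapse = " | "))
    m <- regmatches(line[1],
                    regexec("^([.()]+)\\s+\\(\\s*(-?[0-9]+\\.?[0-9]*)\\s*\\)",
                            line[1]))[[1]]
    if (length(m) != 3L)
        stop("could not parse RNAfold structure line: ", line[1])
    list(partner = .db_to_partner(m[2]), dG = as.numeric(m[3]))
}

#' Predict the minimum-free-energy structure of a sequence
#'
#' Deterministic for a fixed backend: repeated calls return the identical
#' structure and energy.  The toy backend is exactly optimal under its own
#' energy model and never returns isolated (lonely) pairs.
#'
#' @param seq RNA sequence (string over A/C/G/U; T is converted with a
#'   warning).
#' @param backend `"toy"` (default) or `"vienna"`.
#' @param cache optional [newFoldCache()] environment.
#' @return a [FoldResult-class].
#' @examples
#' foldSequence("GGGGAAAACCCC")
#' @export
foldSequence <- function(seq, backend = c("toy", "vienna"), cache = NULL) {
    backend <- .backend_check(backend)
    s <- .seq_norm(seq)
    raw <- .fold_raw(s, backend, cache)
    new("FoldResult",
        structure = new("PairTable", len = length(raw$partner),
                        pairs = .partner_to_pairs(raw$partner)),
        dG = raw$dG, backend = backend)
}

#' Describe a folding backend
#'
#' Stable descriptor string (name, version, parameter digest) embedded in
#' every design report for reproducibility.
#'
#' @param backend `"toy"` or `"vienna"`.
#' @return character string.
#' @export
backendInfo <- function(backend = c("toy", "vienna")) {
    backend <- .backend_check(backend)
    if (backend == "toy") return(.TOY_INFO)
    ver <- tryCatch(
        system2("RNAfold", "--version", stdout = TRUE)[1],
        error = function(e) "RNAfold (version unknown)")
    paste0(ver, ", default temperature and dangles")
}

#' @rdname accessors
#' @export
setMethod("foldedStructure", "FoldResult", function(x) x@structure)

#' @rdname accessors
#' @export
setMethod("freeEnergy", "FoldResult", function(x) x@dG)

#' @rdname accessors
#' @export
setMethod("dotBracket", "FoldResult", function(x) renderDotBracket(x@structure))

setMethod("show", "FoldResult", function(object) {
    cat(sprintf("FoldResult [%s]\n  %s (%.2f)\n", object@backend,
                renderDotBracket(object@structure), object@dG))
})
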