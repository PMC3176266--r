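## Random target-structure fixture generator and benchmark panel builder.

## distribute `extra` units over `n` slots uniformly at random
.rand_split <- function(extra, n) {
    out <- integer(n)
    if (extra > 0L) {
        slots <- sample.int(n, extra, replace = TRUE)
        tab <- tabulate(slots, nbins = n)
        out <- out + tab
    }
    out
}

#' Generate a random valid target structure
#'
#' Produces a seeded-deterministic [PairTable-class] of the requested
#' topology class: `"hairpin"` (one helix), `"bulged"` (two helices
#' separated by a bulge or interior loop) or `"multiloop"` (an outer helix
#' enclosing two hairpin branches).  All emitted structures satisfy the
#' parser's constraints (balanced, minimum hairpin loop of 3) and contain
#' no lonely pairs (every helix has >= 2 stacked pairs).
#'
#' @param length total structure length; minimum 8 for `"hairpin"`, 12 for
#'   `"bulged"`, 18 for `"multiloop"`.
#' @param complexity topology class.
#' @param seed optional seed applied via [set.seed()]; `NULL` uses the
#'   current RNG stream.
#' @return a [PairTable-class].
#' @examples
#' renderDotBracket(genStructure(12, "hairpin", seed = 1))
#' @export
genStructure <- function(length, complexity = c("hairpin", "bulged", "multiloop"),
                         seed = NULL) {
    complexity <- match.arg(complexity)
    length <- as.integer(length)
    if (length < 8L) stop("'length' must be >= 8")
    if (!is.null(seed)) set.seed(seed)
    db <- switch(complexity,
        hairpin = .gen_hairpin(length),
        bulged = .gen_bulged(length),
        multiloop = .gen_multiloop(length))
    parseDotBracket(db)
}

.db_assemble <- function(h, inner, e5 = 0L, e3 = 0L) {
    paste0(strrep(".", e5), strrep("(", h), inner, strrep(")", h),
           strrep(".", e3))
}

.gen_hairpin <- function(L) {
    ## L = e + 2h + u with h >= 2, u >= 3, e >= 0
    extra <- .rand_split(L - 7L, 3L)            # to (h pairs, loop, external)
    h <- 2L + extra[1L] %/% 2L
    u <- L - 2L * h - extra[3L]
    e <- L - 2L * h - u
    e5 <- sample.int(e + 1L, 1L) - 1L
    .db_assemble(h, strrep(".", u), e5, e - e5)
}

.gen_bulged <- function(L) {
    if (L < 12L) stop(sprintf("'length' %d too short for a bulged structure (min 12)", L))
    ## L = e + 2h1 + b + 2h2 + u : h1,h2 >= 2, b >= 1, u >= 3
    extra <- .rand_split(L - 12L, 5L)           # (h1, h2, bulge, loop, external)
    h1 <- 2L + extra[1L] %/% 2L
    h2 <- 2L + extra[2L] %/% 2L
    b <- 1L + extra[3L]
    u <- 3L + extra[4L]
    e <- L - (2L * h1 + 2L * h2 + b + u)
    hp <- .db_assemble(h2, strrep(".", u))
    kind <- if (b >= 2L) sample(c("b5", "b3", "int"), 1L) else sample(c("b5", "b3"), 1L)
    inner <- switch(kind,
        b5 = paste0(strrep(".", b), hp),
        b3 = paste0(hp, strrep(".", b)),
        int = {
            b5 <- sample.int(b - 1L, 1L)
            paste0(strrep(".", b5), hp, strrep(".", b - b5))
        })
    e5 <- sample.int(e + 1L, 1L) - 1L
    .db_assemble(h1, inner, e5, e - e5)
}

.gen_multiloop <- function(L) {
    if (L < 18L) stop(sprintf("'length' %d too short for a multiloop structure (min 18)", L))
    ## L = e + 2h0 + m + sum_branch(2hi + ui); two branches
    extra <- .rand_split(L - 18L, 8L)  # h0,h1,h2,u1,u2,m1,m2,external
    h0 <- 2L + extra[1L] %/% 2L
    h1 <- 2L + extra[2L] %/% 2L
    h2 <- 2L + extra[3L] %/% 2L
    u1 <- 3L + extra[4L]
    u2 <- 3L + extra[5L]
    used <- 2L * (h0 + h1 + h2) + u1 + u2
    m <- min(extra[6L] + extra[7L], L - used)
    e <- L - used - m
    gaps <- .rand_split(m, 3L)         # before / between / after the branches
    inner <- paste0(strrep(".", gaps[1L]),
                    .db_assemble(h1, strrep(".", u1)),
                    strrep(".", gaps[2L]),
                    .db_assemble(h2, strrep(".", u2)),
                    strrep(".", gaps[3L]))
    e5 <- sample.int(e + 1L, 1L) - 1L
    .db_assemble(h0, inner, e5, e - e5)
}

#' Generate a benchmark panel of achievable design goals
#'
#' Builds `n` random targets (lengths drawn within `lengths`, cycling over
#' the three topology classes) that are demonstrably achievable under the
#' selected backend: for each candidate target an adaptive walk is run from
#' up to `tries` random compatible starts, and the target is kept only if
#' some walk reaches base-pair distance 0 (otherwise the next seeded
#' candidate is drawn).  The walk's end sequence becomes the panel's
#' reference; its measured free energy and neutrality define the desired
#' values of the returned [DesignGoals-class], so the goals are realisable
#' by construction.
#'
#' @param n panel size.
#' @param lengths length-2 integer range of target lengths.
#' @param seed RNG seed (panel is deterministic given the seed).
#' @param backend `"toy"` or `"vienna"`.
#' @param tries random starts attempted per candidate target.
#' @return list of `n` entries, each a list with elements `goals`
#'   ([DesignGoals-class]), `reference` (sequence string), `complexity`,
#'   and `length`.
#' @export
generateBenchmarkPanel <- function(n = 10L, lengths = c(30L, 60L), seed = 1L,
                                   backend = "toy", tries = 3L) {
    backend <- .backend_check(backend)
    if (exists(".Random.seed", envir = globalenv())) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(seed)
    classes <- c("hairpin", "bulged", "multiloop")
    cache <- newFoldCache()
    panel <- vector("list", n)
    i <- 0L
    while (i < n) {
        cls <- classes[i %% 3L + 1L]
        Lmin <- max(c(hairpin = 8L, bulged = 12L, multiloop = 18L)[cls],
                    lengths[1L])
        L <- sample(seq.int(Lmin, lengths[2L]), 1L)
        target <- genStructure(L, cls)
        probe <- designGoals(target, dG = 0, neutrality = 0.5)
        ref <- NULL
        for (t in seq_len(tries)) {
            ## same walk operator as the design procedure's first phase, so
            ## the reference values are typical of its attractor family
            s <- adaptiveWalk(initSequence(probe), probe, score = "bp",
                              pairMoves = TRUE, backend = backend,
                              cache = cache)
            if (.bp_dist_partner(.pairs_to_partner(target@pairs, target@len),
                                 .fold_raw(s, backend, cache)$partner) == 0L) {
                ref <- s
                break
            }
        }
        if (is.null(ref)) next  # unattainable under this backend; redraw
        i <- i + 1L
        panel[[i]] <- list(
            goals = designGoals(target,
                                dG = .fold_raw(ref, backend, cache)$dG,
                                neutrality = .neutrality_raw(ref, backend, cache)),
            reference = ref, complexity = cls, length = L)
    }
    panel
}
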