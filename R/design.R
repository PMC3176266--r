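## Core design algorithm: four-term objective, adaptive-walk initialisation
## (phase 1) and simulated annealing with look-ahead sampling (phase 2).

#' Construct design goals
#'
#' Bundles the target structure (its weighted Shapiro shape is derived
#' automatically) with the desired minimum free energy and neutrality.
#'
#' @param structure target secondary structure: dot-bracket string or
#'   [PairTable-class].
#' @param dG desired minimum free energy, kcal/mol.
#' @param neutrality desired neutrality in `[0, 1]`.
#' @return a [DesignGoals-class].
#' @export
designGoals <- function(structure, dG, neutrality) {
    if (is.character(structure)) structure <- parseDotBracket(structure)
    stopifnot(is(structure, "PairTable"))
    new("DesignGoals", targetStructure = structure,
        targetShape = toShapiro(structure, weighted = TRUE),
        desiredDG = as.numeric(dG), desiredNeutrality = as.numeric(neutrality))
}

#' Construct objective weights
#'
#' @param neutrality,dG,shape,bp non-negative term weights; see
#'   [ObjectiveWeights-class] for the rationale behind the defaults.
#' @return an [ObjectiveWeights-class].
#' @export
objectiveWeights <- function(neutrality = 500, dG = 2, shape = 50, bp = 1) {
    new("ObjectiveWeights", neutrality = as.numeric(neutrality),
        dG = as.numeric(dG), shape = as.numeric(shape), bp = as.numeric(bp))
}

#' Construct an annealing configuration
#'
#' @param steps annealing steps (CLI `-i`).
#' @param lookahead maximum Hamming distance of sampled neighbours (CLI
#'   `-t`).
#' @param samplesPerStep candidates per step; `NA` uses the sequence length.
#' @param tieEnds bias proposals to keep the outermost helix ends
#'   complementary (CLI `-e`).
#' @param T0 initial temperature; `NA` calibrates it from a warm-up phase.
#' @param alpha cooling factor in `(0, 1)`; `NA` targets a final
#'   temperature of `1e-3 * T0`.
#' @param exactObjective evaluate neutrality for every candidate rather
#'   than only for the screened candidate promoted each step.
#' @param seed RNG seed recorded with results.
#' @return an [AnnealConfig-class].
#' @export
annealConfig <- function(steps = 200L, lookahead = 4L, samplesPerStep = NA,
                         tieEnds = FALSE, T0 = NA, alpha = NA,
                         exactObjective = FALSE, seed = NA) {
    new("AnnealConfig", steps = as.integer(steps),
        lookahead = as.integer(lookahead),
        samplesPerStep = as.integer(samplesPerStep),
        tieEnds = isTRUE(tieEnds), T0 = as.numeric(T0),
        alpha = as.numeric(alpha), exactObjective = isTRUE(exactObjective),
        seed = as.integer(seed))
}

#' Combined design objective
#'
#' Weighted sum of the four attribute gaps:
#' `w_n |eta_d - eta| + w_dG |dG_d - dG| + w_shape d_tree + w_bp d_bp`.
#' Non-negative; zero iff every term vanishes.
#'
#' @param neutrality observed neutrality in `[0, 1]`.
#' @param dG observed minimum free energy, kcal/mol.
#' @param shapeDistance Shapiro tree-edit distance to the target shape.
#' @param bpDist base-pair distance to the target structure.
#' @param goals a [DesignGoals-class].
#' @param weights an [ObjectiveWeights-class].
#' @return non-negative number.
#' @export
objectiveValue <- function(neutrality, dG, shapeDistance, bpDist, goals,
                           weights = objectiveWeights()) {
    stopifnot(is(goals, "DesignGoals"), is(weights, "ObjectiveWeights"))
    weights@neutrality * abs(goals@desiredNeutrality - neutrality) +
        weights@dG * abs(goals@desiredDG - dG) +
        weights@shape * shapeDistance +
        weights@bp * bpDist
}

#' Random start sequence compatible with the target structure
#'
#' Paired positions draw one of the six canonical pair types AU/UA/GC/CG/
#' GU/UG uniformly (so GU appears with probability 1/6 per paired
#' position); unpaired positions draw uniformly from A/C/G/U.  Uses the
#' global RNG stream.
#'
#' @param goals a [DesignGoals-class].
#' @return RNA sequence string.
#' @export
initSequence <- function(goals) {
    stopifnot(is(goals, "DesignGoals"))
    pt <- goals@targetStructure
    chars <- sample(.RNA_BASES, pt@len, replace = TRUE)
    if (nrow(pt@pairs)) {
        types <- sample(.ALLOWED_PAIRS, nrow(pt@pairs), replace = TRUE)
        chars[pt@pairs[, 1L] + 1L] <- substr(types, 1L, 1L)
        chars[pt@pairs[, 2L] + 1L] <- substr(types, 2L, 2L)
    }
    paste(chars, collapse = "")
}

## -- internal evaluation machinery --------------------------------------

## per-target shape context: flattened target tree plus the cache-key
## prefix that scopes memoised shape distances to this target
.shape_ctx <- function(goals, cache) {
    tdb <- renderDotBracket(goals@targetStructure)
    key <- paste0("#tflat:", tdb)
    if (!is.null(cache)) {
        hit <- cache[[key]]
        if (!is.null(hit)) return(hit)
    }
    ctx <- list(flat = .flatten_tree(goals@targetShape@root),
                prefix = paste0("#shape:", tdb, ":"))
    if (!is.null(cache)) cache[[key]] <- ctx
    ctx
}

## shape distance of a folded structure (dot-bracket string) to the target
## shape, memoised by the dot-bracket string; raw nested-list path under
## the default cost model (no S4 construction on the hot path)
.shape_dist_db <- function(db, goals, cache, ctx = NULL) {
    if (is.null(ctx)) ctx <- .shape_ctx(goals, cache)
    key <- paste0(ctx$prefix, db)
    if (!is.null(cache)) {
        hit <- cache[[key]]
        if (!is.null(hit)) return(hit)
    }
    f <- .flatten_tree(.shapiro_root(.db_to_partner(db), weighted = TRUE))
    d <- .ted_default_flat(f, ctx$flat)
    if (!is.null(cache)) cache[[key]] <- d
    d
}

## structural metrics of a vector of sequences: dG, bp distance to the
## target, folded dot-bracket, optionally shape distance and the
## structure-terms-only ("screen") objective.  The toy backend folds the
## whole batch in compiled code.
.eval_struct_batch <- function(seqs, goals, weights, backend, cache,
                               target_partner, with_shape = TRUE) {
    if (backend == "toy") {
        r <- c_toy_eval_batch(seqs, target_partner)
        out <- list(dG = r$dG, bpd = r$bpd, db = as.character(r$db))
    } else {
        evs <- lapply(seqs, function(s) .fold_raw(s, backend, cache))
        out <- list(
            dG = vapply(evs, function(e) e$dG, numeric(1)),
            bpd = vapply(evs, function(e)
                .bp_dist_partner(target_partner, e$partner), numeric(1)),
            db = vapply(evs, function(e) .partner_to_db(e$partner),
                        character(1)))
    }
    if (with_shape) {
        ctx <- .shape_ctx(goals, cache)
        out$sd <- vapply(out$db, .shape_dist_db, numeric(1), goals = goals,
                         cache = cache, ctx = ctx, USE.NAMES = FALSE)
        out$screen <- weights@dG * abs(goals@desiredDG - out$dG) +
            weights@shape * out$sd + weights@bp * out$bpd
    }
    out
}

## structural metrics of one sequence
.eval_struct <- function(seq, goals, weights, backend, cache, target_partner) {
    b <- .eval_struct_batch(seq, goals, weights, backend, cache, target_partner)
    list(dG = b$dG[1], bpd = b$bpd[1], sd = b$sd[1], db = b$db[1],
         screen = b$screen[1])
}

.neutrality_cached <- function(seq, backend, cache) {
    key <- paste0("#eta:", backend, ":", seq)
    if (!is.null(cache)) {
        hit <- cache[[key]]
        if (!is.null(hit)) return(hit)
    }
    v <- .neutrality_raw(seq, backend, cache)
    if (!is.null(cache)) cache[[key]] <- v
    v
}

## full four-term objective of a sequence; returns metrics too
.eval_full <- function(seq, goals, weights, backend, cache, target_partner) {
    m <- .eval_struct(seq, goals, weights, backend, cache, target_partner)
    m$eta <- .neutrality_cached(seq, backend, cache)
    m$F <- m$screen + weights@neutrality * abs(goals@desiredNeutrality - m$eta)
    m
}

## -- phase 1: adaptive walk ---------------------------------------------

#' Adaptive walk toward the target structure
#'
#' Greedy local search: repeatedly scans all `3 L` single-point mutants (in
#' position order, residues A<C<G<U) and moves to the best strictly
#' improving neighbour; stops at a perfect match or a local minimum.  With
#' `score = "bp"` (default, the phase-1 initialiser) the criterion is the
#' base-pair distance of the folded mutant to the target structure; with
#' `score = "objective"` it is the full four-term objective.
#'
#' With `pairMoves = TRUE` the scanned neighbourhood additionally contains
#' coordinated pair-type swaps: both residues of a target base pair are
#' replaced together by one of the five alternative canonical pair types.
#' Treating a paired position as a single variable is how inverse-folding
#' walks classically move through sequence space without transiting
#' incompatible intermediates.
#'
#' @param seq start sequence (must be compatible with the target).
#' @param goals a [DesignGoals-class].
#' @param score `"bp"` or `"objective"`.
#' @param weights an [ObjectiveWeights-class] (used for
#'   `score = "objective"`).
#' @param pairMoves also scan coordinated pair-type swaps.
#' @param backend,cache as in [foldSequence()].
#' @param trace optional environment; accepted sequences are appended to
#'   `trace$moves`.
#' @return the final sequence (its score is <= the start's score).
#' @export
adaptiveWalk <- function(seq, goals, score = c("bp", "objective"),
                         weights = objectiveWeights(), pairMoves = FALSE,
                         backend = c("toy", "vienna"), cache = NULL,
                         trace = NULL) {
    score <- match.arg(score)
    backend <- .backend_check(backend)
    cur <- .seq_norm(seq)
    tp <- .pairs_to_partner(goals@targetStructure@pairs,
                            goals@targetStructure@len)
    if (nchar(cur) != length(tp))
        stop("sequence and target structure lengths differ")
    score_batch <- if (score == "bp") {
        function(seqs) .eval_struct_batch(seqs, goals, weights, backend,
                                          cache, tp, with_shape = FALSE)$bpd
    } else {
        function(seqs) {
            b <- .eval_struct_batch(seqs, goals, weights, backend, cache, tp)
            etas <- vapply(seqs, .neutrality_cached, numeric(1),
                           backend = backend, cache = cache, USE.NAMES = FALSE)
            b$screen + weights@neutrality * abs(goals@desiredNeutrality - etas)
        }
    }
    cur_s <- score_batch(cur)
    repeat {
        if (cur_s == 0) break
        chars <- strsplit(cur, "", fixed = TRUE)[[1]]
        mutants <- .enumerate_mutants(chars)
        if (pairMoves)
            mutants <- c(mutants,
                         .enumerate_pair_swaps(chars,
                                               goals@targetStructure@pairs))
        ms <- score_batch(mutants)
        best <- which.min(ms)
        if (ms[best] >= cur_s) break
        cur <- mutants[best]
        cur_s <- ms[best]
        if (!is.null(trace)) trace$moves <- c(trace$moves, cur)
    }
    cur
}

## -- proposal moves -------------------------------------------------------

#' Sample a look-ahead neighbour
#'
#' Draws a Hamming distance `d` uniformly from `1..lookahead`, picks `d`
#' distinct positions, and replaces each with a uniformly chosen different
#' residue.  Uses the global RNG stream.
#'
#' @param seq RNA sequence string.
#' @param lookahead maximum Hamming distance (>= 1, <= sequence length).
#' @return mutated sequence at Hamming distance in `1..lookahead`.
#' @export
sampleNeighbor <- function(seq, lookahead = 4L) {
    s <- .seq_norm(seq)
    L <- nchar(s)
    lookahead <- as.integer(lookahead)
    if (lookahead < 1L) stop("'lookahead' must be >= 1")
    if (lookahead > L)
        stop(sprintf("requested look-ahead distance %d exceeds sequence length %d",
                     lookahead, L))
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    d <- sample.int(lookahead, 1L)
    pos <- sample.int(L, d)
    for (p in pos) {
        choices <- setdiff(.RNA_BASES, chars[p])
        chars[p] <- choices[sample.int(3L, 1L)]
    }
    paste(chars, collapse = "")
}

## batched neighbour sampling for the annealing loop: one strsplit, n draws
.sample_neighbors <- function(chars, lookahead, n) {
    L <- length(chars)
    out <- character(n)
    for (q in seq_len(n)) {
        m <- chars
        d <- sample.int(lookahead, 1L)
        pos <- sample.int(L, d)
        for (p in pos) {
            choices <- .RNA_BASES[.RNA_BASES != m[p]]
            m[p] <- choices[sample.int(3L, 1L)]
        }
        out[q] <- paste(m, collapse = "")
    }
    out
}

.PAIR_PARTNERS <- list(A = "U", C = "G", G = c("C", "U"), U = c("A", "G"))

#' Tie the ends of the structure together
#'
#' Proposal bias for the `-e` option: if the target's outermost helix pairs
#' the 5'-most with the 3'-most paired position, make the corresponding
#' residues of `seq` complementary (AU/GC/GU) by resampling one of the two
#' ends; a no-op when they already pair or when the target has no such
#' exterior pair.  Uses the global RNG stream.
#'
#' @param seq RNA sequence string.
#' @param goals a [DesignGoals-class].
#' @return possibly modified sequence.
#' @export
tieEnds <- function(seq, goals) {
    s <- .seq_norm(seq)
    p <- goals@targetStructure@pairs
    if (nrow(p) == 0L) return(s)
    i <- min(p[, 1L]); j <- max(p[, 2L])
    if (!any(p[, 1L] == i & p[, 2L] == j)) return(s)  # no exterior helix pair
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    if (paste0(chars[i + 1L], chars[j + 1L]) %in% .ALLOWED_PAIRS) return(s)
    if (sample.int(2L, 1L) == 1L) {  # resample the 5' residue
        opts <- .PAIR_PARTNERS[[chars[j + 1L]]]
        chars[i + 1L] <- opts[sample.int(length(opts), 1L)]
    } else {
        opts <- .PAIR_PARTNERS[[chars[i + 1L]]]
        chars[j + 1L] <- opts[sample.int(length(opts), 1L)]
    }
    paste(chars, collapse = "")
}

## heat-bath candidate selection: draw index i with probability
## proportional to exp(-score_i / T); at T = 0 this degenerates to the
## deterministic first minimum (no RNG draw)
.boltzmann_pick <- function(scores, T) {
    if (T <= 0) return(which.min(scores))
    w <- exp(-(scores - min(scores)) / T)
    sample.int(length(scores), 1L, prob = w)
}

## -- phase 2: simulated annealing ----------------------------------------

#' Simulated annealing over the four-term objective
#'
#' Runs `steps` annealing steps with geometric cooling
#' `T_k = T0 * alpha^k`.  Each step draws `samplesPerStep` candidates via
#' [sampleNeighbor()] (when `lookahead == 1` and
#' `samplesPerStep >= 3 L`, the 1-neighbourhood is enumerated exhaustively
#' instead, in the same deterministic order as [adaptiveWalk()]), scores
#' them with the structural terms, promotes one by heat-bath selection at
#' the current temperature (probability proportional to
#' `exp(-score / T_k)`; the first minimum when `T_k = 0`), evaluates the
#' full objective (including neutrality) for the promoted candidate, and
#' accepts it if the objective improves, or with probability
#' `exp(-dF / T_k)` otherwise.  With `T0 = 0` the whole step is purely
#' greedy.  The best-so-far sequence, whose objective is non-increasing
#' over the run, is returned.
#'
#' @param start start sequence (typically the [adaptiveWalk()] result).
#' @param goals a [DesignGoals-class].
#' @param weights an [ObjectiveWeights-class].
#' @param config an [AnnealConfig-class].
#' @param backend,cache as in [foldSequence()].
#' @param trace optional environment; accepted sequences are appended to
#'   `trace$moves` and the best objective after each step to `trace$bestF`.
#' @return a [DesignResult-class].
#' @export
anneal <- function(start, goals, weights = objectiveWeights(),
                   config = annealConfig(), backend = c("toy", "vienna"),
                   cache = NULL, trace = NULL) {
    backend <- .backend_check(backend)
    stopifnot(is(goals, "DesignGoals"), is(weights, "ObjectiveWeights"),
              is(config, "AnnealConfig"))
    cur <- .seq_norm(start)
    L <- nchar(cur)
    tp <- .pairs_to_partner(goals@targetStructure@pairs,
                            goals@targetStructure@len)
    if (L != length(tp)) stop("sequence and target structure lengths differ")
    if (is.null(cache)) cache <- newFoldCache()
    sps <- if (is.na(config@samplesPerStep)) L else config@samplesPerStep
    exhaustive <- config@lookahead == 1L && sps >= 3L * L

    cur_m <- .eval_full(cur, goals, weights, backend, cache, tp)
    best <- cur; best_m <- cur_m

    T0 <- config@T0
    if (is.na(T0)) {
        ## warm-up: scale so a median-sized uphill move is accepted with
        ## probability ~1/2 at the start
        props <- .sample_neighbors(strsplit(cur, "", fixed = TRUE)[[1]],
                                   config@lookahead, 50L)
        pb <- .eval_struct_batch(props, goals, weights, backend, cache, tp)
        deltas <- abs(pb$screen - cur_m$screen)
        med <- median(deltas[deltas > 0])
        T0 <- if (is.na(med) || med == 0) 1 else med / log(2)
    }
    alpha <- if (is.na(config@alpha)) exp(log(1e-3) / config@steps)
             else config@alpha

    for (k in seq_len(config@steps)) {
        Tk <- T0 * alpha^k
        if (exhaustive) {
            cands <- .enumerate_mutants(strsplit(cur, "", fixed = TRUE)[[1]])
        } else {
            cands <- .sample_neighbors(strsplit(cur, "", fixed = TRUE)[[1]],
                                       config@lookahead, sps)
            if (config@tieEnds)
                cands <- vapply(cands, tieEnds, character(1), goals = goals,
                                USE.NAMES = FALSE)
        }
        b <- .eval_struct_batch(cands, goals, weights, backend, cache, tp)
        if (config@exactObjective) {
            etas <- vapply(cands, .neutrality_cached, numeric(1),
                           backend = backend, cache = cache, USE.NAMES = FALSE)
            fs <- b$screen +
                weights@neutrality * abs(goals@desiredNeutrality - etas)
            sel <- .boltzmann_pick(fs, Tk)
            cand_m <- list(dG = b$dG[sel], bpd = b$bpd[sel], sd = b$sd[sel],
                           db = b$db[sel], screen = b$screen[sel],
                           eta = etas[sel], F = fs[sel])
        } else {
            ## two-stage evaluation: neutrality (the dominant cost, 3L
            ## folds per sequence) only for the candidate promoted from
            ## the structural screen
            sel <- .boltzmann_pick(b$screen, Tk)
            eta <- .neutrality_cached(cands[sel], backend, cache)
            cand_m <- list(dG = b$dG[sel], bpd = b$bpd[sel], sd = b$sd[sel],
                           db = b$db[sel], screen = b$screen[sel], eta = eta,
                           F = b$screen[sel] + weights@neutrality *
                               abs(goals@desiredNeutrality - eta))
        }
        dF <- cand_m$F - cur_m$F
        accept <- dF < 0 || (Tk > 0 && runif(1L) < exp(-dF / Tk))
        if (accept) {
            cur <- cands[sel]; cur_m <- cand_m
            if (!is.null(trace)) trace$moves <- c(trace$moves, cur)
            if (cur_m$F < best_m$F) { best <- cur; best_m <- cur_m }
        }
        if (!is.null(trace)) trace$bestF <- c(trace$bestF, best_m$F)
    }

    best_partner <- .db_to_partner(best_m$db)
    new("DesignResult", sequence = best,
        predicted = new("FoldResult",
            structure = new("PairTable", len = L,
                            pairs = .partner_to_pairs(best_partner)),
            dG = best_m$dG, backend = backend),
        neutrality = new("NeutralityValue", value = min(1, best_m$eta),
                         mutantsEvaluated = 3L * L),
        shapeDistance = best_m$sd, bpDist = as.integer(best_m$bpd),
        objective = best_m$F, rankScore = best_m$sd, seed = config@seed)
}

## Deep greedy polish used as the third stage of designSequences: a
## shape-preserving descent on the full objective over single-point
## mutants plus coordinated pair-type swaps, with a two-move stall breaker
## for the shallow barriers that separate neighbouring compositions
## (weaken/strengthen one pair, repair neutrality elsewhere).  Neutrality
## is only evaluated for moves whose structural score could possibly beat
## the current objective (F >= screen, so screen >= F_cur moves can never
## win) -- an exact filter, not an approximation.
.deep_polish <- function(seq, goals, weights, backend, cache,
                         max_moves = 400L, sweep_cap = 40L,
                         stall_width = 40L, stall_depth = 100L,
                         tol = 0.5) {
    tp <- .pairs_to_partner(goals@targetStructure@pairs,
                            goals@targetStructure@len)
    pairs <- goals@targetStructure@pairs
    cur <- seq
    cur_m <- .eval_full(cur, goals, weights, backend, cache, tp)
    moves <- 0L
    full_of <- function(seqs, b, idx) {
        etas <- vapply(seqs[idx], .neutrality_cached, numeric(1),
                       backend = backend, cache = cache, USE.NAMES = FALSE)
        b$screen[idx] + weights@neutrality *
            abs(goals@desiredNeutrality - etas)
    }
    ## descend until the objective sits below tol -- half a base-pair unit,
    ## i.e. a quarter kcal/mol or a 0.001 neutrality gap, well under any
    ## meaningful attribute difference
    while (moves < max_moves && cur_m$F > tol) {
        chars <- strsplit(cur, "", fixed = TRUE)[[1]]
        cand <- c(.enumerate_mutants(chars),
                  .enumerate_pair_swaps(chars, pairs))
        b <- .eval_struct_batch(cand, goals, weights, backend, cache, tp)
        elig <- which(b$sd == 0 & b$screen < cur_m$F - 1e-9)
        elig <- elig[order(b$screen[elig])]
        elig <- elig[seq_len(min(sweep_cap, length(elig)))]
        if (length(elig)) {
            fs <- full_of(cand, b, elig)
            win <- which.min(fs)
            if (fs[win] < cur_m$F - 1e-9) {
                cur <- cand[elig[win]]
                cur_m <- .eval_full(cur, goals, weights, backend, cache, tp)
                moves <- moves + 1L
                next
            }
        }
        ## single moves exhausted: probe two-move combinations through the
        ## structurally closest intermediates; the first move may be
        ## screen-uphill (overshoot), only the combination must improve
        step1 <- which(b$sd == 0)
        step1 <- step1[order(b$screen[step1])]
        step1 <- step1[seq_len(min(stall_width, length(step1)))]
        best2 <- cur_m$F
        best2_seq <- NULL
        for (k in step1) {
            ch1 <- strsplit(cand[k], "", fixed = TRUE)[[1]]
            cand2 <- c(.enumerate_mutants(ch1),
                       .enumerate_pair_swaps(ch1, pairs))
            b2 <- .eval_struct_batch(cand2, goals, weights, backend, cache, tp)
            elig2 <- which(b2$sd == 0 & b2$screen < best2 - 1e-9)
            if (!length(elig2)) next
            elig2 <- elig2[order(b2$screen[elig2])]
            elig2 <- elig2[seq_len(min(stall_depth, length(elig2)))]
            fs2 <- full_of(cand2, b2, elig2)
            w2 <- which.min(fs2)
            if (fs2[w2] < best2 - 1e-9) {
                best2 <- fs2[w2]
                best2_seq <- cand2[elig2[w2]]
            }
        }
        if (is.null(best2_seq)) {
            ## escalate once more: three-move probe.  The remaining stalls
            ## need an odd-parity pair swap at a helix end plus two
            ## neutrality repairs; a two-deep beam cannot see them.
            best3 <- cur_m$F
            best3_seq <- NULL
            lvl1 <- step1[seq_len(min(12L, length(step1)))]
            for (k in lvl1) {
                ch1 <- strsplit(cand[k], "", fixed = TRUE)[[1]]
                c2 <- c(.enumerate_mutants(ch1),
                        .enumerate_pair_swaps(ch1, pairs))
                bb2 <- .eval_struct_batch(c2, goals, weights, backend, cache,
                                          tp)
                mid <- which(bb2$sd == 0)
                mid <- mid[order(bb2$screen[mid])]
                mid <- mid[seq_len(min(12L, length(mid)))]
                for (q in mid) {
                    ch2 <- strsplit(c2[q], "", fixed = TRUE)[[1]]
                    c3 <- c(.enumerate_mutants(ch2),
                            .enumerate_pair_swaps(ch2, pairs))
                    b3 <- .eval_struct_batch(c3, goals, weights, backend,
                                             cache, tp)
                    e3 <- which(b3$sd == 0 & b3$screen < best3 - 1e-9)
                    if (!length(e3)) next
                    e3 <- e3[order(b3$screen[e3])]
                    e3 <- e3[seq_len(min(30L, length(e3)))]
                    fs3 <- full_of(c3, b3, e3)
                    w3 <- which.min(fs3)
                    if (fs3[w3] < best3 - 1e-9) {
                        best3 <- fs3[w3]
                        best3_seq <- c3[e3[w3]]
                    }
                }
            }
            if (is.null(best3_seq)) break
            cur <- best3_seq
            cur_m <- .eval_full(cur, goals, weights, backend, cache, tp)
            moves <- moves + 3L
            next
        }
        cur <- best2_seq
        cur_m <- .eval_full(cur, goals, weights, backend, cache, tp)
        moves <- moves + 2L
    }
    cur
}

## build a fully evaluated DesignResult for a sequence
.make_result <- function(seq, goals, weights, backend, cache, seed) {
    tp <- .pairs_to_partner(goals@targetStructure@pairs,
                            goals@targetStructure@len)
    m <- .eval_full(seq, goals, weights, backend, cache, tp)
    partner <- .db_to_partner(m$db)
    new("DesignResult", sequence = seq,
        predicted = new("FoldResult",
            structure = new("PairTable", len = nchar(seq),
                            pairs = .partner_to_pairs(partner)),
            dG = m$dG, backend = backend),
        neutrality = new("NeutralityValue", value = min(1, m$eta),
                         mutantsEvaluated = 3L * nchar(seq)),
        shapeDistance = m$sd, bpDist = as.integer(m$bpd),
        objective = m$F, rankScore = m$sd, seed = as.integer(seed))
}

## -- multi-run driver ----------------------------------------------------

#' Design sequences for a target shape and physical attributes
#'
#' Runs the full design procedure `nRuns` times with independent seeds
#' derived from `seed`.  Each run chains three stages: random compatible
#' starts refined by an adaptive walk toward the target structure
#' ([initSequence()], [adaptiveWalk()] with coordinated pair-swap moves,
#' restarted until the walk realises the target exactly or `maxInitTries`
#' is exhausted); simulated annealing over the four-term objective
#' ([anneal()]); and a deep greedy polish on the full objective that
#' closes the residual free-energy and neutrality gaps remaining when the
#' cooled chain stops accepting moves.  A run repeats this pipeline from
#' fresh random starts (up to three rounds, keeping the best result,
#' exact-shape results taking precedence) until the objective converges
#' below the polish floor, so occasional runs trapped in a poor basin get
#' independent retries.  Results are
#' sorted ascending by `rankScore` (the Shapiro tree-edit distance between
#' the design's predicted shape and the target shape), with ties broken by
#' objective and then seed.  A fixed `seed` makes the output fully
#' reproducible.
#'
#' @param goals a [DesignGoals-class].
#' @param nRuns number of independent runs (>= 1).
#' @param weights an [ObjectiveWeights-class].
#' @param config an [AnnealConfig-class]; its `seed` slot is ignored here.
#' @param backend `"toy"` or `"vienna"`.
#' @param seed master RNG seed.
#' @param maxInitTries phase-1 attempts per run: the adaptive walk is
#'   restarted from fresh random starts until it reaches base-pair
#'   distance 0 (or the attempts are exhausted, in which case the closest
#'   start found is used), mirroring the repeated-inverse-folding way a
#'   good initial candidate is obtained.
#' @return a [DesignSet-class].
#' @examples
#' goals <- designGoals("((((....))))", dG = -18, neutrality = 0.9)
#' designSequences(goals, nRuns = 2, config = annealConfig(steps = 20),
#'                 seed = 1)
#' @export
designSequences <- function(goals, nRuns = 10L, weights = objectiveWeights(),
                            config = annealConfig(), backend = c("toy", "vienna"),
                            seed = 1L, maxInitTries = 100L) {
    backend <- .backend_check(backend)
    stopifnot(is(goals, "DesignGoals"), nRuns >= 1L)
    if (exists(".Random.seed", envir = globalenv())) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(seed)
    run_seeds <- sample.int(.Machine$integer.max, nRuns)
    cache <- newFoldCache()
    results <- vector("list", nRuns)
    tp <- .pairs_to_partner(goals@targetStructure@pairs,
                            goals@targetStructure@len)
    for (r in seq_len(nRuns)) {
        set.seed(run_seeds[r])
        cfg <- config
        cfg@seed <- run_seeds[r]
        ## One run = up to three full restarts ("rounds") of the
        ## three-stage pipeline, keeping the best result; a new round only
        ## starts while the objective has not converged below the polish
        ## floor, so converged runs pay for a single round.  Within a
        ## round: phase-1 walk restarts until the target structure is
        ## realised exactly; simulated annealing; then a deep greedy
        ## polish from both the annealing optimum and the phase-1
        ## sequence (the annealing chain can migrate to a
        ## structure-shifted basin of equal shape it cannot leave, while
        ## the phase-1 basin often holds the better refined optimum).
        ## The designed sequence must conform strictly with the target
        ## shape, so exact-shape candidates take precedence; ties resolve
        ## by objective.
        prefer <- function(a, b) {
            if (is.null(a)) return(b)
            if ((b@shapeDistance == 0 || a@shapeDistance > 0) &&
                b@objective < a@objective) return(b)
            if (a@shapeDistance > 0 && b@shapeDistance == 0) return(b)
            a
        }
        best <- NULL
        for (round in 1:3) {
            s1 <- NULL
            s1_d <- Inf
            for (t in seq_len(max(1L, maxInitTries))) {
                w <- adaptiveWalk(initSequence(goals), goals, score = "bp",
                                  pairMoves = TRUE, backend = backend,
                                  cache = cache)
                d <- .eval_struct_batch(w, goals, weights, backend, cache,
                                        tp, with_shape = FALSE)$bpd
                if (d < s1_d) { s1 <- w; s1_d <- d }
                if (s1_d == 0) break
            }
            res <- anneal(s1, goals, weights, cfg, backend, cache)
            p1 <- .make_result(
                .deep_polish(s1, goals, weights, backend, cache),
                goals, weights, backend, cache, run_seeds[r])
            best <- prefer(best, p1)
            if (!identical(res@sequence, s1) &&
                res@objective < best@objective) {
                p2 <- .make_result(
                    .deep_polish(res@sequence, goals, weights, backend, cache),
                    goals, weights, backend, cache, run_seeds[r])
                best <- prefer(best, p2)
            }
            if (best@objective <= 0.5) break
        }
        results[[r]] <- best
    }
    ord <- order(vapply(results, function(x) x@rankScore, numeric(1)),
                 vapply(results, function(x) x@objective, numeric(1)),
                 vapply(results, function(x) x@seed, integer(1)))
    new("DesignSet", results = results[ord], goals = goals,
        weights = weights, config = config, backend = backend)
}

## -- methods --------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("designedSequence", "DesignResult", function(x) x@sequence)

#' @rdname accessors
#' @export
setMethod("freeEnergy", "DesignResult", function(x) x@predicted@dG)

#' @rdname accessors
#' @export
setMethod("neutralityScore", "DesignResult", function(x) x@neutrality@value)

#' @rdname accessors
#' @export
setMethod("shapeDistance", "DesignResult", function(x) x@shapeDistance)

#' @rdname accessors
#' @export
setMethod("bpDeviation", "DesignResult", function(x) x@bpDist)

#' @rdname accessors
#' @export
setMethod("objectiveScore", "DesignResult", function(x) x@objective)

#' @rdname accessors
#' @export
setMethod("rankScore", "DesignResult", function(x) x@rankScore)

#' @rdname accessors
#' @export
setMethod("designResults", "DesignSet", function(x) x@results)

setMethod("show", "DesignResult", function(object) {
    cat(sprintf(
        "DesignResult (seed %s)\n  %s\n  %s (%.2f kcal/mol)\n  neutrality %.4f | shape dist %g | bp dist %d | objective %.3f\n",
        object@seed, object@sequence,
        renderDotBracket(object@predicted@structure), object@predicted@dG,
        object@neutrality@value, object@shapeDistance, object@bpDist,
        object@objective))
})

setMethod("show", "DesignSet", function(object) {
    cat(sprintf("DesignSet of %d results [backend %s]\n",
                length(object@results), object@backend))
    df <- as.data.frame(object)
    print(df[, c("rank", "sequence", "dG", "neutrality", "shape_dist",
                 "bp_dist", "objective")])
})

#' Tabulate a DesignSet
#'
#' @param x a [DesignSet-class].
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return `data.frame` with one row per design, in rank order.
#' @method as.data.frame DesignSet
#' @export
as.data.frame.DesignSet <- function(x, row.names = NULL, optional = FALSE, ...) {
    res <- x@results
    data.frame(
        rank = seq_along(res),
        sequence = vapply(res, function(r) r@sequence, character(1)),
        structure = vapply(res, function(r)
            renderDotBracket(r@predicted@structure), character(1)),
        dG = vapply(res, function(r) r@predicted@dG, numeric(1)),
        neutrality = vapply(res, function(r) r@neutrality@value, numeric(1)),
        shape_dist = vapply(res, function(r) r@shapeDistance, numeric(1)),
        bp_dist = vapply(res, function(r) r@bpDist, integer(1)),
        objective = vapply(res, function(r) r@objective, numeric(1)),
        rank_score = vapply(res, function(r) r@rankScore, numeric(1)),
        seed = vapply(res, function(r) r@seed, integer(1)),
        stringsAsFactors = FALSE)
}
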