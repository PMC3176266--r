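## Independent oracles used across the suite.  These deliberately avoid the
## package's internal code paths: structure enumeration and energies are
## recomputed from first principles, and the tree edit distance oracle is a
## naive memoised forest recursion rather than the keyroot DP.

## pair strength table of the toy energy model, restated independently
oracle_strength <- function(a, b) {
    key <- paste0(a, b)
    if (key %in% c("GC", "CG")) return(3)
    if (key %in% c("AU", "UA")) return(2)
    if (key %in% c("GU", "UG")) return(1)
    0
}

## energy of a structure (two-column 0-based pair matrix, rows sorted by i)
## under the toy model: each stacked adjacency (i,j)/(i+1,j-1) contributes
## minus the sum of the two pair strengths
oracle_energy <- function(chars, pairs) {
    if (nrow(pairs) == 0L) return(0)
    key <- paste(pairs[, 1L], pairs[, 2L])
    e <- 0
    for (r in seq_len(nrow(pairs))) {
        i <- pairs[r, 1L]; j <- pairs[r, 2L]
        if (paste(i + 1L, j - 1L) %in% key) {
            e <- e - (oracle_strength(chars[i + 1L], chars[j + 1L]) +
                      oracle_strength(chars[i + 2L], chars[j]))
        }
    }
    e
}

## enumerate every valid structure of a sequence: non-crossing, minimum
## hairpin loop 3, every helix at least 2 stacked pairs.  Returns a list of
## pair matrices (with duplicates removed).
oracle_enumerate <- function(chars) {
    n <- length(chars)
    can <- function(i, j) j - i >= 4 && oracle_strength(chars[i + 1L], chars[j + 1L]) > 0
    memo <- new.env(parent = emptyenv())
    rec <- function(i, j) {
        if (j - i + 1L < 7L) return(list(matrix(integer(0), ncol = 2L)))
        key <- paste(i, j)
        hit <- memo[[key]]
        if (!is.null(hit)) return(hit)
        ## position i unpaired
        out <- rec(i + 1L, j)
        ## helix starting with pair (i, k)
        for (k in seq.int(i + 6L, j)) {
            h <- 0L
            while (can(i + h, k - h)) h <- h + 1L
            if (h < 2L) next
            for (hh in 2L:h) {
                helix <- cbind(i + 0L:(hh - 1L), k - 0L:(hh - 1L))
                inner <- rec(i + hh, k - hh)
                right <- rec(k + 1L, j)
                for (si in inner) for (sr in right)
                    out[[length(out) + 1L]] <- rbind(helix, si, sr)
            }
        }
        memo[[key]] <- out
        out
    }
    structs <- rec(0L, n - 1L)
    keys <- vapply(structs, function(p)
        paste(p[order(p[, 1L]), , drop = FALSE], collapse = ","), character(1))
    structs[!duplicated(keys)]
}

## brute-force mfe: minimum oracle energy over all enumerated structures
oracle_fold_min <- function(seq) {
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    min(vapply(oracle_enumerate(chars), function(p) oracle_energy(chars, p),
               numeric(1)))
}

## base-pair distance between pair matrices, recomputed as a set operation
oracle_bp_dist <- function(pa, pb, n) {
    ka <- pa[, 1L] * n + pa[, 2L]
    kb <- pb[, 1L] * n + pb[, 2L]
    length(setdiff(ka, kb)) + length(setdiff(kb, ka))
}

## brute-force neutrality: explicit mutant list + enumeration folding.
## When a mutant has several co-optimal mfe structures, the similarity is
## bracketed over all of them, so the function returns an interval
## [lo, hi]; the two ends coincide whenever every fold is unique.
## `unique_wt` reports whether the wild-type optimum itself is unique
## (comparisons are only well defined when it is).
oracle_neutrality <- function(seq, mutant_order = NULL) {
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    L <- length(chars)
    argmins <- function(ch) {
        ss <- oracle_enumerate(ch)
        es <- vapply(ss, function(p) oracle_energy(ch, p), numeric(1))
        ss[es == min(es)]
    }
    wts <- argmins(chars)
    wt <- wts[[1L]]
    bases <- c("A", "C", "G", "U")
    muts <- list()
    for (pos in seq_len(L)) for (b in bases) {
        if (b == chars[pos]) next
        m <- chars; m[pos] <- b
        muts[[length(muts) + 1L]] <- m
    }
    if (!is.null(mutant_order)) muts <- muts[mutant_order]
    sims <- lapply(muts, function(m) {
        s <- vapply(argmins(m), function(p)
            1 - oracle_bp_dist(wt, p, L) / L, numeric(1))
        range(s)
    })
    lo <- mean(vapply(sims, `[`, numeric(1), 1L))
    hi <- mean(vapply(sims, `[`, numeric(1), 2L))
    list(lo = lo, hi = hi, unique_wt = length(wts) == 1L)
}

## ---- tree oracles -------------------------------------------------------

shapiro_node <- function(type, weight, children = list())
    list(type = type, weight = as.integer(weight), children = children)

## naive recursive forest edit distance with memoisation; leftmost-root
## decomposition, independent of the Zhang-Shasha keyroot DP
oracle_tree_dist <- function(a, b, costs = defaultCosts()) {
    render <- function(f) paste(vapply(f, function(t)
        paste0(t$type, t$weight, "(",
               render(t$children), ")"), character(1)), collapse = "+")
    memo <- new.env(parent = emptyenv())
    ind <- function(t) {
        costs@indel(t$type, t$weight) +
            sum(vapply(t$children, ind, numeric(1)), 0)
    }
    fd <- function(f1, f2) {
        if (length(f1) == 0L && length(f2) == 0L) return(0)
        key <- paste(render(f1), "|", render(f2))
        hit <- memo[[key]]
        if (!is.null(hit)) return(hit)
        v <- if (length(f1) == 0L) {
            sum(vapply(f2, ind, numeric(1)))
        } else if (length(f2) == 0L) {
            sum(vapply(f1, ind, numeric(1)))
        } else {
            t1 <- f1[[1L]]; r1 <- f1[-1L]
            t2 <- f2[[1L]]; r2 <- f2[-1L]
            min(costs@indel(t1$type, t1$weight) + fd(c(t1$children, r1), f2),
                costs@indel(t2$type, t2$weight) + fd(f1, c(t2$children, r2)),
                costs@relabel(t1$type, t1$weight, t2$type, t2$weight) +
                    fd(t1$children, t2$children) + fd(r1, r2))
        }
        memo[[key]] <- v
        v
    }
    fd(list(a@root), list(b@root))
}

## random ordered labelled tree with n_extra nodes under an R root; node
## types/weights drawn from the Shapiro alphabet
random_tree <- function(n_extra, weighted = TRUE) {
    root <- shapiro_node("R", if (weighted) 0L else NA_integer_)
    nodes <- list(integer(0))  # paths to attachment points
    for (i in seq_len(n_extra)) {
        path <- nodes[[sample.int(length(nodes), 1L)]]
        node <- shapiro_node(sample(c("E", "S", "H", "B", "I", "M"), 1L),
                             if (weighted) sample.int(5L, 1L) else NA_integer_)
        ## attach under 'path'
        root <- local({
            attach_at <- function(nd, p) {
                if (length(p) == 0L) {
                    nd$children[[length(nd$children) + 1L]] <- node
                    nd
                } else {
                    nd$children[[p[1L]]] <- attach_at(nd$children[[p[1L]]], p[-1L])
                    nd
                }
            }
            attach_at(root, path)
        })
        ## record the new node's path
        parent_children <- local({
            count_at <- function(nd, p) {
                if (length(p) == 0L) length(nd$children)
                else count_at(nd$children[[p[1L]]], p[-1L])
            }
            count_at(root, path)
        })
        nodes[[length(nodes) + 1L]] <- c(path, parent_children)
    }
    new("ShapiroTree", root = root)
}

## random RNA sequence
random_seq <- function(L) paste(sample(c("A", "C", "G", "U"), L,
                                       replace = TRUE), collapse = "")
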