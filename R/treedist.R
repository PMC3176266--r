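## Ordered tree edit distance between Shapiro trees (Zhang-Shasha keyroot
## dynamic programme).  Only the optimal cost is returned; no edit script.

## flatten a tree into postorder arrays: type, weight, lml (index of the
## leftmost leaf descendant, postorder, 1-based)
.flatten_tree <- function(root) {
    n <- 0L
    cnt <- function(nd) {
        n <<- n + 1L
        for (ch in nd$children) cnt(ch)
    }
    cnt(root)
    type <- character(n); weight <- integer(n); lml <- integer(n)
    i <- 0L
    rec <- function(node) {
        first <- NA_integer_
        for (ch in node$children) {
            f <- rec(ch)
            if (is.na(first)) first <- f
        }
        i <<- i + 1L
        type[i] <<- node$type
        weight[i] <<- node$weight
        lml[i] <<- if (is.na(first)) i else first
        lml[i]
    }
    rec(root)
    list(type = type, weight = weight, lml = lml, n = n)
}

.keyroots <- function(lml) {
    n <- length(lml)
    seen <- logical(n)
    kr <- integer(0)
    for (i in n:1) {
        if (!seen[lml[i]]) {
            kr <- c(kr, i)
            seen[lml[i]] <- TRUE
        }
    }
    sort(kr)
}

#' Default edit-cost model for weighted Shapiro trees
#'
#' Insertion/deletion of a node costs its weight; relabelling two nodes of
#' the same type costs the absolute weight difference, of different types
#' the weight sum.  Unweighted nodes count as weight 1; the root `R`
#' carries weight 0, so `relabel(R, R) = 0` always.
#'
#' @return an [EditCosts-class].
#' @examples
#' co <- defaultCosts()
#' co@relabel("S", 3L, "S", 5L)  # 2
#' co@relabel("H", 3L, "B", 3L)  # 6
#' @export
defaultCosts <- function() {
    w <- function(type, weight) ifelse(type == "R", 0,
                                       ifelse(is.na(weight), 1, weight))
    new("EditCosts",
        indel = function(type, weight) w(type, weight),
        relabel = function(type_a, weight_a, type_b, weight_b) {
            ifelse(type_a == type_b,
                   abs(w(type_a, weight_a) - w(type_b, weight_b)),
                   w(type_a, weight_a) + w(type_b, weight_b))
        })
}

#' Ordered tree edit distance between two Shapiro trees
#'
#' Minimum total cost of node insertions, deletions and relabelings
#' transforming one ordered tree into the other while preserving ancestry
#' and sibling order (Zhang-Shasha keyroot dynamic programme).  This is the
#' shape term of the design objective and the ranking score of the design
#' output list.
#'
#' @param a,b [ShapiroTree-class] objects (or linear Shapiro strings, or
#'   dot-bracket strings which are first converted via [toShapiro()]).
#' @param costs an [EditCosts-class]; default [defaultCosts()].
#' @return non-negative number; 0 iff the trees are identical under the
#'   cost model.
#' @examples
#' treeEditDistance("((H3)S3)R", "((H4)S3)R")  # 1
#' @export
treeEditDistance <- function(a, b, costs = defaultCosts()) {
    a <- .as_shapiro(a)
    b <- .as_shapiro(b)
    stopifnot(is(costs, "EditCosts"))
    t1 <- .flatten_tree(a@root)
    t2 <- .flatten_tree(b@root)
    ## precompute numeric cost tables so the DP is pure arithmetic
    del1 <- vapply(seq_len(t1$n),
                   function(i) costs@indel(t1$type[i], t1$weight[i]), numeric(1))
    del2 <- vapply(seq_len(t2$n),
                   function(i) costs@indel(t2$type[i], t2$weight[i]), numeric(1))
    rel <- outer(seq_len(t1$n), seq_len(t2$n),
                 function(i, j) costs@relabel(t1$type[i], t1$weight[i],
                                              t2$type[j], t2$weight[j]))
    .zhang_shasha(t1, t2, del1, del2, rel)
}

.as_shapiro <- function(x) {
    if (is(x, "ShapiroTree")) return(x)
    if (is(x, "PairTable")) return(toShapiro(x))
    if (is.character(x) && length(x) == 1L) {
        if (grepl("^[.()]+$", x)) return(toShapiro(x))
        return(parseShapiro(x))
    }
    stop("expected a ShapiroTree, PairTable, shapiro string or dot-bracket string")
}

## fast internal path under the default cost model: numeric del vectors
## and relabel matrix computed vectorised, no S4 construction
.ted_default_flat <- function(f1, f2) {
    w1 <- ifelse(f1$type == "R", 0, ifelse(is.na(f1$weight), 1, f1$weight))
    w2 <- ifelse(f2$type == "R", 0, ifelse(is.na(f2$weight), 1, f2$weight))
    same <- outer(f1$type, f2$type, "==")
    rel <- outer(w1, w2, "+")
    rel[same] <- abs(outer(w1, w2, "-"))[same]
    .zhang_shasha(f1, f2, w1, w2, rel)
}

.zhang_shasha <- function(t1, t2, del1, del2, rel) {
    n1 <- t1$n; n2 <- t2$n
    l1 <- t1$lml; l2 <- t2$lml
    td <- matrix(0, n1, n2)
    for (i in .keyroots(l1)) {
        for (j in .keyroots(l2)) {
            ## forest distance over subforests l1[i]..i and l2[j]..j
            li <- l1[i]; lj <- l2[j]
            m <- i - li + 1L; k <- j - lj + 1L
            fd <- matrix(0, m + 1L, k + 1L)
            for (x in seq_len(m)) fd[x + 1L, 1L] <- fd[x, 1L] + del1[li + x - 1L]
            for (y in seq_len(k)) fd[1L, y + 1L] <- fd[1L, y] + del2[lj + y - 1L]
            for (x in seq_len(m)) {
                ix <- li + x - 1L
                for (y in seq_len(k)) {
                    jy <- lj + y - 1L
                    if (l1[ix] == li && l2[jy] == lj) {
                        d <- min(fd[x, y + 1L] + del1[ix],
                                 fd[x + 1L, y] + del2[jy],
                                 fd[x, y] + rel[ix, jy])
                        fd[x + 1L, y + 1L] <- d
                        td[ix, jy] <- d
                    } else {
                        px <- l1[ix] - li     # size of prefix forest before subtree ix
                        py <- l2[jy] - lj
                        fd[x + 1L, y + 1L] <- min(fd[x, y + 1L] + del1[ix],
                                                  fd[x + 1L, y] + del2[jy],
                                                  fd[px + 1L, py + 1L] + td[ix, jy])
                    }
                }
            }
        }
    }
    td[n1, n2]
}
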