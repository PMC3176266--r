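## Coarse-grained (Shapiro) shape of a secondary structure.
##
## Decomposition rules: maximal runs of stacked pairs form S nodes (weight =
## number of pairs); the loop each helix closes becomes H (hairpin), B
## (bulge: unpaired bases on exactly one strand), I (interior: both strands)
## or M (multiloop: >= 2 emanating helices, weight = unpaired bases, may be
## 0); external unpaired bases are pooled into a single exterior-loop node
## E that carries the exterior helices as children and hangs off the root
## R (when there are no external unpaired bases the helices hang off R
## directly).  Children are ordered 5'->3'.  This matches ViennaRNA's
## b2shapiro output modulo its outermost parenthesis wrap, which we drop.

.shapiro_node <- function(type, weight, children = list()) {
    list(type = type, weight = as.integer(weight), children = children)
}

## scan a region [a, b] (0-based, inclusive) at one nesting level; returns
## list(children = list of S subtrees, unpaired = count)
.scan_region <- function(partner, a, b, weighted) {
    children <- list()
    unpaired <- 0L
    k <- a
    while (k <= b) {
        j <- partner[k + 1L]
        if (j < 0L) {
            unpaired <- unpaired + 1L
            k <- k + 1L
        } else {
            children[[length(children) + 1L]] <- .helix_node(partner, k, j, weighted)
            k <- j + 1L
        }
    }
    list(children = children, unpaired = unpaired)
}

## helix with outer pair (i, j); follow stacked pairs inward, then classify
## the loop the helix closes
.helix_node <- function(partner, i, j, weighted) {
    h <- 1L
    while (partner[i + h + 1L] == j - h) h <- h + 1L
    inner <- .scan_region(partner, i + h, j - h, weighted)
    nb <- length(inner$children)
    w <- function(x) if (weighted) as.integer(x) else NA_integer_
    loop <- if (nb == 0L) {
        .shapiro_node("H", w(inner$unpaired))
    } else if (nb == 1L) {
        ## bulge if the unpaired bases sit on one strand only
        ci <- inner$children[[1L]]$.span
        left <- ci[1L] - (i + h)
        right <- (j - h) - ci[2L]
        type <- if (left > 0L && right > 0L) "I" else "B"
        .shapiro_node(type, w(inner$unpaired), inner$children)
    } else {
        .shapiro_node("M", w(inner$unpaired), inner$children)
    }
    loop$children <- lapply(loop$children, function(x) { x$.span <- NULL; x })
    node <- .shapiro_node("S", w(h), list(loop))
    node$.span <- c(i, j)   # consumed (and stripped) by the caller
    node
}

#' Coarse-grained Shapiro shape of a structure
#'
#' Decomposes a secondary structure into its motif tree: helices (`S`),
#' hairpin loops (`H`), bulges (`B`), interior loops (`I`), multiloops
#' (`M`), external bases (`E`) under the root `R`.  With `weighted = TRUE`
#' (default) `S` nodes carry the number of stacked pairs and loop nodes the
#' number of unpaired bases; `weighted = FALSE` drops all weights.
#'
#' @param pt a [PairTable-class] or dot-bracket string.
#' @param weighted keep motif sizes as node weights?
#' @return a [ShapiroTree-class].
#' @examples
#' shapiroToString(toShapiro("(((...)))"))   # "((H3)S3)R"
#' @export
toShapiro <- function(pt, weighted = TRUE) {
    if (is.character(pt)) pt <- parseDotBracket(pt)
    stopifnot(is(pt, "PairTable"))
    partner <- .pairs_to_partner(pt@pairs, pt@len)
    new("ShapiroTree", root = .shapiro_root(partner, weighted))
}

## internal: nested-list Shapiro root straight from a partner vector
.shapiro_root <- function(partner, weighted = TRUE) {
    n <- length(partner)
    ext <- .scan_region(partner, 0L, n - 1L, weighted)
    children <- lapply(ext$children, function(x) { x$.span <- NULL; x })
    if (ext$unpaired > 0L)
        children <- list(.shapiro_node(
            "E", if (weighted) ext$unpaired else NA_integer_, children))
    .shapiro_node("R", if (weighted) 0L else NA_integer_, children)
}

.render_node <- function(node) {
    inner <- paste(vapply(node$children, .render_node, character(1)),
                   collapse = "")
    lab <- if (node$type == "R" || is.na(node$weight)) node$type
           else paste0(node$type, node$weight)
    if (node$type == "R") paste0(inner, "R") else paste0("(", inner, lab, ")")
}

#' Canonical linear rendering of a Shapiro tree
#'
#' Children are rendered left-to-right in 5'->3' order; each non-root node
#' appears as `(childrenLABELweight)` and the string ends in `R`.
#' [parseShapiro()] inverts this rendering.
#'
#' @param t a [ShapiroTree-class].
#' @return character string, e.g. `"((H3)S3)R"`.
#' @export
shapiroToString <- function(t) {
    stopifnot(is(t, "ShapiroTree"))
    .render_node(t@root)
}

#' Parse a linear Shapiro string
#'
#' Recursive-descent parser for the rendering produced by
#' [shapiroToString()] (and, after stripping the outermost parenthesis
#' pair, by ViennaRNA's `b2shapiro`).  A string with bare labels (no
#' weights) yields an unweighted tree.
#'
#' @param text linear Shapiro string such as `"((H3)S3)R"`.
#' @return a [ShapiroTree-class].
#' @export
parseShapiro <- function(text) {
    if (!is.character(text) || length(text) != 1L || is.na(text))
        stop("'text' must be a single character string")
    chars <- strsplit(trimws(text), "", fixed = TRUE)[[1]]
    n <- length(chars)
    pos <- 1L
    err <- function(msg) stop(sprintf("shapiro parse error at position %d: %s",
                                      pos, msg))
    peek <- function() if (pos <= n) chars[pos] else ""
    parse_content <- function() {
        children <- list()
        while (peek() == "(") {
            pos <<- pos + 1L
            children[[length(children) + 1L]] <- parse_content()
            if (peek() != ")") err("expected ')'")
            pos <<- pos + 1L
        }
        type <- peek()
        if (!type %in% .shapiro_types) err("expected a node label (R/E/S/H/B/I/M)")
        pos <<- pos + 1L
        digits <- ""
        while (grepl("^[0-9]$", peek())) {
            digits <- paste0(digits, peek())
            pos <<- pos + 1L
        }
        weight <- if (nzchar(digits)) as.integer(digits) else NA_integer_
        if (type == "R" && is.na(weight)) weight <- NA_integer_
        .shapiro_node(type, weight, children)
    }
    root <- parse_content()
    if (pos <= n) err("trailing characters")
    if (root$type != "R") err("string must end in 'R'")
    ## a tree is weighted iff any node carries a weight; normalise R's weight
    weighted <- .tree_weighted(root)
    root$weight <- if (weighted) 0L else NA_integer_
    new("ShapiroTree", root = root)
}

.tree_weighted <- function(node) {
    if (node$type != "R" && !is.na(node$weight)) return(TRUE)
    for (ch in node$children) if (.tree_weighted(ch)) return(TRUE)
    FALSE
}

## total positions accounted for by a tree: 2 * S weights + loop weights
.tree_positions <- function(node) {
    own <- if (is.na(node$weight)) 0L
           else if (node$type == "S") 2L * node$weight
           else node$weight
    own + sum(vapply(node$children, .tree_positions, integer(1)), 0L)
}

setMethod("show", "ShapiroTree", function(object) {
    cat("ShapiroTree:", .render_node(object@root), "\n")
})
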