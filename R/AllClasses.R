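#' @import methods
#' @importFrom stats median runif
#' @importFrom utils write.table
#' @useDynLib RNAShapeDesign, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' PairTable: a pseudoknot-free RNA secondary structure
#'
#' A secondary structure represented as its length and the set of base
#' pairs, stored as a two-column integer matrix of 0-based `(i, j)` indices
#' with `i < j`.  Validity enforces the standard constraints: every position
#' in at most one pair, no crossing pairs (pseudoknots), and a minimum
#' hairpin loop of 3 unpaired bases (`j - i >= 4`).
#'
#' @slot len single integer, number of positions (>= 1).
#' @slot pairs integer matrix with two columns (0-based `i`, `j`).
#'
#' @seealso [parseDotBracket()], [renderDotBracket()], [bpDistance()]
#' @export
setClass("PairTable",
    representation(len = "integer", pairs = "matrix"),
    prototype(len = 1L, pairs = matrix(integer(0), ncol = 2L)))

setValidity("PairTable", function(object) {
    L <- object@len
    p <- object@pairs
    if (length(L) != 1L || is.na(L) || L < 1L)
        return("'len' must be a single positive integer")
    if (!is.numeric(p) || ncol(p) != 2L)
        return("'pairs' must be a two-column integer matrix")
    if (nrow(p) == 0L) return(TRUE)
    i <- p[, 1L]; j <- p[, 2L]
    if (any(is.na(p)) || any(p < 0L) || any(p >= L))
        return("pair indices out of range [0, len)")
    if (any(i >= j)) return("pairs must satisfy i < j")
    if (any(j - i < 4L))
        return("hairpin loop below minimum size: a pair (i, j) needs j - i >= 4")
    if (anyDuplicated(c(i, j)))
        return("a position takes part in more than one pair")
    # crossing check via bracket rendering: a stack discipline must succeed
    partner <- rep.int(-1L, L)
    partner[i + 1L] <- j
    partner[j + 1L] <- i
    open <- integer(0)
    for (k in seq_len(L) - 1L) {
        q <- partner[k + 1L]
        if (q > k) open <- c(open, q)
        else if (q >= 0L) {
            if (length(open) == 0L || open[length(open)] != k)
                return("crossing base pairs (pseudoknot) are not allowed")
            open <- open[-length(open)]
        }
    }
    TRUE
})

#' ShapiroTree: coarse-grained (Shapiro) representation of a structure
#'
#' Ordered, labelled, optionally weighted tree over node types `R` (root),
#' `E` (external unpaired bases), `S` (helix/stack), `H` (hairpin loop),
#' `B` (bulge), `I` (interior loop) and `M` (multiloop).  For `S` the weight
#' counts stacked pairs; for the loop types it counts unpaired bases in the
#' region.  Unweighted trees carry `NA` weights.
#'
#' The tree is stored as a nested list with elements `type`, `weight`, and
#' `children`; use [toShapiro()], [parseShapiro()] and [shapiroToString()]
#' rather than building it by hand.
#'
#' @slot root nested list with elements `type`, `weight`, `children`.
#' @export
setClass("ShapiroTree", representation(root = "list"))

.shapiro_types <- c("R", "E", "S", "H", "B", "I", "M")

.check_shapiro_node <- function(node, depth) {
    if (!is.list(node) || !all(c("type", "weight", "children") %in% names(node)))
        return("each node needs 'type', 'weight' and 'children'")
    if (!node$type %in% .shapiro_types)
        return(sprintf("unknown node type '%s'", node$type))
    if (node$type == "R" && depth > 0L)
        return("'R' may only appear at the root")
    if (!is.na(node$weight) && node$weight < 0L)
        return("node weights must be >= 0")
    for (ch in node$children) {
        msg <- .check_shapiro_node(ch, depth + 1L)
        if (!isTRUE(msg)) return(msg)
    }
    TRUE
}

setValidity("ShapiroTree", function(object) {
    if (length(object@root) == 0L) return("empty tree")
    if (object@root$type != "R") return("root node must have type 'R'")
    .check_shapiro_node(object@root, 0L)
})

#' EditCosts: cost model for ordered tree edit distance
#'
#' @slot indel function of `(type, weight)` returning the cost of inserting
#'   or deleting a node.
#' @slot relabel function of `(type_a, weight_a, type_b, weight_b)` returning
#'   the relabelling cost; must be symmetric with `relabel(a, a) == 0`.
#'
#' @seealso [defaultCosts()], [treeEditDistance()]
#' @export
setClass("EditCosts", representation(indel = "function", relabel = "function"))

#' FoldResult: a predicted minimum-free-energy structure
#'
#' @slot structure a [PairTable-class] of the same length as the query.
#' @slot dG minimum free energy in kcal/mol (0 for the open chain).
#' @slot backend backend identifier the prediction came from.
#' @export
setClass("FoldResult",
    representation(structure = "PairTable", dG = "numeric",
                   backend = "character"))

setValidity("FoldResult", function(object) {
    if (length(object@dG) != 1L || is.na(object@dG))
        return("'dG' must be a single number")
    TRUE
})

#' NeutralityValue: mutational robustness of a sequence
#'
#' Average, over all `3 L` single-point mutants, of the base-pair similarity
#' `1 - d_bp / L` between the mutant's predicted structure and that of the
#' original sequence.  Always in `[0, 1]`.
#'
#' @slot value neutrality in `[0, 1]`.
#' @slot mutantsEvaluated number of mutants folded (`3 L`).
#' @export
setClass("NeutralityValue",
    representation(value = "numeric", mutantsEvaluated = "integer"))

setValidity("NeutralityValue", function(object) {
    v <- object@value
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1 + 1e-12)
        return("'value' must lie in [0, 1]")
    TRUE
})

#' DesignGoals: target shape and physical attributes of a design run
#'
#' @slot targetStructure the target secondary structure ([PairTable-class]).
#' @slot targetShape weighted Shapiro tree derived from the target.
#' @slot desiredDG desired minimum free energy, kcal/mol.
#' @slot desiredNeutrality desired neutrality in `[0, 1]`.
#'
#' @seealso [designGoals()]
#' @export
setClass("DesignGoals",
    representation(targetStructure = "PairTable", targetShape = "ShapiroTree",
                   desiredDG = "numeric", desiredNeutrality = "numeric"))

setValidity("DesignGoals", function(object) {
    n <- object@desiredNeutrality
    if (length(n) != 1L || is.na(n) || n < 0 || n > 1)
        return("'desiredNeutrality' must lie in [0, 1]")
    if (length(object@desiredDG) != 1L || is.na(object@desiredDG))
        return("'desiredDG' must be a single number")
    TRUE
})

#' ObjectiveWeights: weights of the four objective terms
#'
#' The combined objective is
#' `w_neutrality * |eta_d - eta| + w_dG * |dG_d - dG| +
#'  w_shape * d_tree(shape, target shape) + w_bp * d_bp(structure, target)`.
#' Defaults keep the shape term dominant (one tree-edit unit outweighs the
#' typical contribution of every other term) while a 0.01 neutrality gap
#' weighs like a 2.5 kcal/mol free-energy gap.
#'
#' @slot neutrality,dG,shape,bp non-negative reals.
#' @seealso [objectiveWeights()], [objectiveValue()]
#' @export
setClass("ObjectiveWeights",
    representation(neutrality = "numeric", dG = "numeric",
                   shape = "numeric", bp = "numeric"))

setValidity("ObjectiveWeights", function(object) {
    w <- c(object@neutrality, object@dG, object@shape, object@bp)
    if (length(w) != 4L || any(is.na(w)) || any(w < 0))
        return("all four weights must be single non-negative numbers")
    TRUE
})

#' AnnealConfig: simulated-annealing run parameters
#'
#' @slot steps number of annealing steps (CLI `-i`).
#' @slot lookahead maximum Hamming distance of sampled neighbours
#'   (CLI `-t`; default 4).
#' @slot samplesPerStep candidates drawn per step (`NA` = sequence length).
#' @slot tieEnds bias proposals so the outermost helix ends stay
#'   complementary (CLI `-e`).
#' @slot T0 initial temperature; `NA` = calibrated from a warm-up phase so
#'   initial acceptance of a median-sized uphill move is about one half.
#' @slot alpha geometric cooling factor in `(0, 1)`; `NA` = chosen so the
#'   final temperature is `1e-3 * T0`.
#' @slot exactObjective evaluate neutrality for every candidate instead of
#'   screening by the structural terms first.
#' @slot seed RNG seed recorded with results.
#' @seealso [annealConfig()], [anneal()]
#' @export
setClass("AnnealConfig",
    representation(steps = "integer", lookahead = "integer",
                   samplesPerStep = "integer", tieEnds = "logical",
                   T0 = "numeric", alpha = "numeric",
                   exactObjective = "logical", seed = "integer"))

setValidity("AnnealConfig", function(object) {
    if (object@steps < 1L) return("'steps' must be >= 1")
    if (object@lookahead < 1L) return("'lookahead' must be >= 1")
    if (!is.na(object@alpha) && (object@alpha <= 0 || object@alpha >= 1))
        return("'alpha' must lie in (0, 1)")
    if (!is.na(object@T0) && object@T0 < 0) return("'T0' must be >= 0")
    TRUE
})

#' DesignResult: one designed sequence with its measured attributes
#'
#' @slot sequence designed RNA sequence.
#' @slot predicted [FoldResult-class] for the sequence.
#' @slot neutrality [NeutralityValue-class] of the sequence.
#' @slot shapeDistance weighted Shapiro tree-edit distance to the target shape.
#' @slot bpDist base-pair distance to the target structure.
#' @slot objective combined objective value at the returned sequence.
#' @slot rankScore score used to order the output list (tree-edit distance).
#' @slot seed RNG seed of the run that produced this result.
#' @export
setClass("DesignResult",
    representation(sequence = "character", predicted = "FoldResult",
                   neutrality = "NeutralityValue", shapeDistance = "numeric",
                   bpDist = "integer", objective = "numeric",
                   rankScore = "numeric", seed = "integer"))

#' DesignSet: ranked collection of design results
#'
#' Returned by [designSequences()]; results are sorted by ascending
#' `rankScore` (ties: objective, then seed).
#'
#' @slot results list of [DesignResult-class].
#' @slot goals the [DesignGoals-class] used.
#' @slot weights the [ObjectiveWeights-class] used.
#' @slot config the [AnnealConfig-class] used.
#' @slot backend folding backend identifier.
#' @export
setClass("DesignSet",
    representation(results = "list", goals = "DesignGoals",
                   weights = "ObjectiveWeights", config = "AnnealConfig",
                   backend = "character"))
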