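## Design report writers: TSV with a '#'-prefixed header block, JSON
## mirror, and FASTA output of the designed sequences.

.report_header <- function(set) {
    w <- set@weights; g <- set@goals; cfg <- set@config
    c(sprintf("# tool=RNAShapeDesign/%s",
              as.character(utils::packageVersion("RNAShapeDesign"))),
      sprintf("# backend=%s", backendInfo(set@backend)),
      sprintf("# target_structure=%s", renderDotBracket(g@targetStructure)),
      sprintf("# target_shape=%s", shapiroToString(g@targetShape)),
      sprintf("# desired_dG=%g", g@desiredDG),
      sprintf("# desired_neutrality=%g", g@desiredNeutrality),
      sprintf("# weights=neutrality:%g,dG:%g,shape:%g,bp:%g",
              w@neutrality, w@dG, w@shape, w@bp),
      sprintf("# config=steps:%d,lookahead:%d,samplesPerStep:%s,tieEnds:%s,T0:%s,alpha:%s,exactObjective:%s",
              cfg@steps, cfg@lookahead,
              ifelse(is.na(cfg@samplesPerStep), "auto", cfg@samplesPerStep),
              cfg@tieEnds,
              ifelse(is.na(cfg@T0), "auto", cfg@T0),
              ifelse(is.na(cfg@alpha), "auto", cfg@alpha),
              cfg@exactObjective))
}

#' Write a TSV design report
#'
#' A `#`-prefixed header block records the tool version, backend
#' descriptor, goals, weights and configuration; one row per design
#' follows, in rank order.  Every row is recomputable from its sequence
#' plus the backend.
#'
#' @param set a [DesignSet-class].
#' @param path output file path, or `""` for standard output.
#' @return `path`, invisibly.
#' @export
writeReport <- function(set, path = "") {
    stopifnot(is(set, "DesignSet"))
    con <- if (nzchar(path)) file(path, "w") else stdout()
    if (nzchar(path)) on.exit(close(con))
    writeLines(.report_header(set), con)
    df <- as.data.frame(set)
    df$dG <- sprintf("%.2f", df$dG)
    df$neutrality <- sprintf("%.6f", df$neutrality)
    df$objective <- sprintf("%.4f", df$objective)
    writeLines(paste(colnames(df), collapse = "\t"), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Write a JSON design report
#'
#' JSON mirror of [writeReport()]: a `header` object plus a `designs`
#' array.
#'
#' @inheritParams writeReport
#' @return `path`, invisibly.
#' @export
writeReportJSON <- function(set, path) {
    stopifnot(is(set, "DesignSet"))
    w <- set@weights; g <- set@goals; cfg <- set@config
    obj <- list(
        header = list(
            tool = paste0("RNAShapeDesign/",
                          as.character(utils::packageVersion("RNAShapeDesign"))),
            backend = backendInfo(set@backend),
            target_structure = renderDotBracket(g@targetStructure),
            target_shape = shapiroToString(g@targetShape),
            desired_dG = g@desiredDG,
            desired_neutrality = g@desiredNeutrality,
            weights = list(neutrality = w@neutrality, dG = w@dG,
                           shape = w@shape, bp = w@bp),
            config = list(steps = cfg@steps, lookahead = cfg@lookahead,
                          tieEnds = cfg@tieEnds)),
        designs = as.data.frame(set))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Write designed sequences to FASTA
#'
#' Records are named `design_<rank>` with description fields for the
#' predicted free energy, neutrality and shape distance; sequences are
#' wrapped at 60 columns.
#'
#' @param results a [DesignSet-class] or non-empty list of
#'   [DesignResult-class].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(results, path) {
    if (is(results, "DesignSet")) results <- results@results
    if (!is.list(results) || length(results) == 0L)
        stop("'results' must be a non-empty list of DesignResult objects")
    seqs <- Biostrings::RNAStringSet(
        vapply(results, function(r) r@sequence, character(1)))
    names(seqs) <- vapply(seq_along(results), function(i) {
        r <- results[[i]]
        sprintf("design_%d dG=%.2f neutrality=%.4f shape_dist=%g",
                i, r@predicted@dG, r@neutrality@value, r@shapeDistance)
    }, character(1))
    Biostrings::writeXStringSet(seqs, path, width = 60L)
    invisible(path)
}
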