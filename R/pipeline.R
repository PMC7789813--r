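#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis. `mode` picks the default
#' normalization: `"mRNA"` uses TPM (needs gene lengths) with top_n 10 and
#' trio combinations; `"miRNA"` uses CPM with top_n 6 and pair combinations;
#' `"qPCR"` converts a Ct table to 2^-Ct abundances and skips the count-based
#' screen (stability only, on supplied candidates).
#'
#' @param counts path to a count TSV (mRNA/miRNA modes).
#' @param design path to the design TSV.
#' @param lengths path to a gene-length TSV (mRNA mode).
#' @param ct path to a Ct table (qPCR mode).
#' @param mode one of `"mRNA"`, `"miRNA"`, `"qPCR"`.
#' @param p_threshold non-DE retention threshold (default 0.1).
#' @param top_n number of candidates; defaults 10 (mRNA) / 6 (miRNA).
#' @param combo_size sizes of combinations to evaluate; defaults 3 (mRNA) /
#'   2 (miRNA/qPCR).
#' @param combo_strategy `"rank-blocks"` (consecutive blocks of the final
#'   ranking) or `"exhaustive"`.
#' @param scorers stability scorers to run.
#' @param pseudocount pseudocount for zero handling in stability scoring.
#' @param seed integer seed recorded in the manifest.
#' @param out_dir output directory (optional; see [write_report()]).
#' @return a config list of class `exoref_config`.
#' @export
pipeline_config <- function(counts = NULL, design = NULL, lengths = NULL,
                            ct = NULL, mode = c("mRNA", "miRNA", "qPCR"),
                            p_threshold = 0.1, top_n = NULL,
                            combo_size = NULL,
                            combo_strategy = c("rank-blocks", "exhaustive"),
                            scorers = c("cv", "m"), pseudocount = 1,
                            seed = 1L, out_dir = NULL) {
  mode <- match.arg(mode)
  combo_strategy <- match.arg(combo_strategy)
  if (is.null(top_n)) top_n <- if (mode == "miRNA") 6L else 10L
  if (is.null(combo_size)) combo_size <- if (mode == "mRNA") 3L else 2L
  if (p_threshold < 0 || p_threshold > 1)
    stop("p_threshold must be in [0, 1]", call. = FALSE)
  if (top_n < 1) stop("top_n must be >= 1", call. = FALSE)
  if (any(combo_size < 2)) stop("combo sizes must be >= 2", call. = FALSE)
  structure(list(counts = counts, design = design, lengths = lengths, ct = ct,
                 mode = mode, p_threshold = p_threshold, top_n = top_n,
                 combo_size = combo_size, combo_strategy = combo_strategy,
                 scorers = scorers, pseudocount = pseudocount,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "exoref_config")
}

#' Read a pipeline config from a YAML file
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return an `exoref_config` object.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(pipeline_config, vals)
}

#' Evaluate combination stability over a stability table
#'
#' `"rank-blocks"` forms strictly consecutive blocks of the final ranking
#' (ranks 1..k, k+1..2k, ...; a trailing block smaller than k is dropped) —
#' the classical way combination candidates are presented. `"exhaustive"`
#' scores every size-k subset. Both return combinations sorted by ascending
#' AV (most stable first), ties broken by member names.
#'
#' @param stability a data frame from [stability_table()] or
#'   [rank_candidates()] (needs `feature`, `m`, `final_rank`).
#' @param combo_size combination size k (>= 2, <= number of candidates).
#' @param strategy `"rank-blocks"` or `"exhaustive"`.
#' @return data frame with `members` (slash-joined), `av`.
#' @export
evaluate_combos <- function(stability, combo_size = 3,
                            strategy = c("rank-blocks", "exhaustive")) {
  strategy <- match.arg(strategy)
  if (combo_size < 2) stop("combo_size must be >= 2", call. = FALSE)
  if (combo_size > nrow(stability))
    stop("combo_size exceeds number of candidates", call. = FALSE)
  ord <- stability[order(stability$final_rank), , drop = FALSE]
  m <- setNames(ord$m, ord$feature)
  if (strategy == "rank-blocks") {
    nblock <- nrow(ord) %/% combo_size
    sets <- lapply(seq_len(nblock), function(b)
      ord$feature[((b - 1) * combo_size + 1):(b * combo_size)])
  } else {
    sets <- combn(ord$feature, combo_size, simplify = FALSE)
  }
  av <- vapply(sets, function(s) av_combination(m, s)$av, 0)
  members <- vapply(sets, paste, "", collapse = "/")
  out <- data.frame(members = members, av = av, stringsAsFactors = FALSE)
  out[order(out$av, out$members), , drop = FALSE]
}

#' Run the end-to-end reference-candidate pipeline
#'
#' mRNA/miRNA modes: read counts + design (+ lengths), normalize (TPM/CPM),
#' screen each case subtype against controls for non-DE features, intersect,
#' apply the pooled high-expression filter, take the top-n by expression,
#' score stability (CV, M, optional NormFinder) on the normalized values of
#' the candidates, rank by CV+M rank sum, and evaluate combination stability.
#' qPCR mode: read a Ct table, convert to 2^-Ct abundances and run the
#' stability stage only. Reruns with the same config and inputs are
#' bit-identical.
#'
#' @param config an `exoref_config` (or path to a YAML config).
#' @return a `exoref_report` list: `stage_counts`, `screen`, `stability`,
#'   `combos`, `warnings`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "exoref_config"))
    stop("config must come from pipeline_config()", call. = FALSE)
  warnings <- character(0)
  stage <- function(name) message("[exoref] stage: ", name)

  if (config$mode == "qPCR") {
    stage("read Ct table")
    ct <- read_ct_table(config$ct)
    design <- if (!is.null(config$design)) read_design(config$design) else NULL
    stage("Ct -> abundance")
    ab <- ct_to_abundance(ct)
    stage("stability scoring")
    stab <- stability_table(ab, design = design, scorers = config$scorers,
                            pseudocount = config$pseudocount)
    screen <- NULL
    counts_per_stage <- c(input = nrow(ct), candidates = nrow(stab))
  } else {
    stage("read inputs")
    counts <- read_matrix(config$counts)
    design <- read_design(config$design)
    validate_design(design, colnames(counts))
    stage("normalize")
    norm <- if (config$mode == "mRNA") {
      compute_tpm(counts, read_lengths(config$lengths))
    } else {
      compute_cpm(counts)
    }
    stage("screen subtypes")
    scr <- screen_candidates(counts, design, norm,
                             p_threshold = config$p_threshold,
                             top_n = config$top_n)
    screen <- scr$result
    counts_per_stage <- scr$stage_counts
    if (length(scr$candidates) == 0) {
      warnings <- c(warnings, "empty candidate set after screening; no stability stage")
      report <- structure(list(stage_counts = counts_per_stage, screen = screen,
                               stability = NULL, combos = NULL,
                               warnings = warnings,
                               manifest = manifest_of(config)),
                          class = "exoref_report")
      if (!is.null(config$out_dir)) write_report(report, config$out_dir)
      return(report)
    }
    stage("stability scoring")
    sub <- norm[scr$candidates, , drop = FALSE]
    attr(sub, "scale") <- expr_scale(norm)
    stab <- stability_table(sub, design = design, scorers = config$scorers,
                            pseudocount = config$pseudocount)
  }
  stage("combination stability")
  combos <- NULL
  for (k in config$combo_size) {
    if (k <= nrow(stab)) {
      ck <- evaluate_combos(stab, k, config$combo_strategy)
      ck$size <- k
      combos <- rbind(combos, ck)
    } else {
      warnings <- c(warnings, paste0("combo size ", k, " exceeds candidate count"))
    }
  }
  report <- structure(list(stage_counts = counts_per_stage, screen = screen,
                           stability = stab, combos = combos,
                           warnings = warnings, manifest = manifest_of(config)),
                      class = "exoref_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

manifest_of <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  list(config = cfg, seed = config$seed,
       package = as.character(packageVersion("exoref")),
       r_version = paste(R.version$major, R.version$minor, sep = "."))
}

#' Write a pipeline report to disk
#'
#' Emits `screen.tsv`, `stability.tsv`, `combos.tsv` (when present) and
#' `report.json` (stage counts, warnings, manifest). No timestamps, so
#' identical runs produce byte-identical files.
#'
#' @param report an `exoref_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$screen))
    write.table(report$screen, file.path(dir, "screen.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(report$stability))
    write.table(report$stability, file.path(dir, "stability.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(report$combos))
    write.table(report$combos, file.path(dir, "combos.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(stage_counts = as.list(report$stage_counts),
         warnings = report$warnings, manifest = report$manifest),
    file.path(dir, "report.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @export
print.exoref_report <- function(x, ...) {
  cat("exoref pipeline report\n")
  cat("stage counts:\n")
  for (n in names(x$stage_counts))
    cat(sprintf("  %-18s %d\n", n, x$stage_counts[[n]]))
  if (!is.null(x$stability)) {
    cat("top candidates (by CV+M rank sum):\n")
    print(utils::head(x$stability[, c("feature", "cv", "m", "rank_sum",
                                      "final_rank")], 10), row.names = FALSE)
  }
  if (!is.null(x$combos)) {
    cat("best combination:", x$combos$members[1],
        sprintf("(AV = %.4f)\n", x$combos$av[1]))
  }
  for (w in x$warnings) cat("warning:", w, "\n")
  invisible(x)
}
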