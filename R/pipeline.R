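#' Build a pipeline run configuration
#'
#' @param fasta Path to the candidate protein FASTA.
#' @param out_dir Output directory.
#' @param panel_fasta,panel_labels Optional reference panel paths (FASTA +
#'   two-column TSV id/label); required for subgroup placement.
#' @param variants `"canonical"` or `"extended"` heptapeptide set.
#' @param window Zinc-finger search window (residues).
#' @param n_boot Bootstrap replicates for the placement tree (0 = none).
#' @param seed Integer seed recorded in all outputs.
#' @param expression Optional expression TSV path.
#' @param contrasts Optional named list of `c(numerator, denominator)`
#'   column pairs.
#' @param lfc_threshold |log2FC| cutoff for direction calls.
#' @param ct Optional Ct table TSV path.
#' @param ct_target,ct_reference,ct_calibrator qPCR analysis settings.
#' @return A list of class `wrky_config`.
#' @export
wrky_config <- function(fasta, out_dir, panel_fasta = NULL,
                        panel_labels = NULL, variants = "canonical",
                        window = 80L, n_boot = 0L, seed = 1L,
                        expression = NULL, contrasts = NULL,
                        lfc_threshold = 1, ct = NULL, ct_target = NULL,
                        ct_reference = "Actin", ct_calibrator = NULL) {
  cfg <- list(fasta = fasta, out_dir = out_dir, panel_fasta = panel_fasta,
              panel_labels = panel_labels, variants = variants,
              window = as.integer(window), n_boot = as.integer(n_boot),
              seed = as.integer(seed), expression = expression,
              contrasts = contrasts, lfc_threshold = lfc_threshold,
              ct = ct, ct_target = ct_target, ct_reference = ct_reference,
              ct_calibrator = ct_calibrator)
  class(cfg) <- "wrky_config"
  cfg
}

#' Run the full WRKY analysis pipeline
#'
#' Orchestrates scan, classification, motif annotation, placement tree and
#' (optionally) expression analytics, writing plain-text reports (TSV,
#' JSON, newick) plus a run log to the output directory. Any stage error
#' aborts the run with the stage named.
#'
#' @param config A `wrky_config` (or list with the same fields).
#' @return Invisibly, a list with the in-memory results and output paths.
#' @export
run_wrky_pipeline <- function(config) {
  cfg <- config
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  log_lines <- c(sprintf("wrkyscan %s",
                         as.character(utils::packageVersion("wrkyscan"))),
                 sprintf("seed: %d", cfg$seed))
  paths <- list()

  records <- stage("read", read_fasta(cfg$fasta))
  variants <- wrky_variants(cfg$variants)
  panel <- NULL
  if (!is.null(cfg$panel_fasta)) {
    if (is.null(cfg$panel_labels))
      stop("stage 'panel' failed: panel_fasta given without panel_labels")
    panel <- stage("panel", read_reference_panel(cfg$panel_fasta,
                                                 cfg$panel_labels))
  }

  assignments <- stage("classify",
                       classify_all(records, panel = panel,
                                    variants = variants, window = cfg$window,
                                    n_boot = cfg$n_boot, seed = cfg$seed))
  domains <- attr(assignments, "domains")
  paths$domains <- file.path(cfg$out_dir, "domains.tsv")
  write_tsv(domains, paths$domains)
  paths$assignments <- file.path(cfg$out_dir, "assignments.tsv")
  write_tsv(as.data.frame(assignments), paths$assignments)
  paths$counts <- file.path(cfg$out_dir, "group_counts.json")
  jsonlite::write_json(as.list(group_counts(assignments)), paths$counts,
                       auto_unbox = TRUE)
  tree <- attr(assignments, "tree")
  if (!is.null(tree)) {
    paths$tree <- file.path(cfg$out_dir, "placement_tree.nwk")
    write_newick(tree, paths$tree)
  }
  log_lines <- c(log_lines,
                 sprintf("proteins: %d, domains: %d", nrow(records),
                         nrow(domains)),
                 sprintf("counts: %s",
                         paste(names(group_counts(assignments)),
                               group_counts(assignments), sep = "=",
                               collapse = " ")))

  motifs <- stage("motifs", annotate_motifs(records))
  paths$motifs <- file.path(cfg$out_dir, "motifs.tsv")
  write_tsv(motifs, paths$motifs)

  expr_out <- NULL
  if (!is.null(cfg$expression)) {
    expr_out <- stage("expression", {
      expr <- read_expression_table(cfg$expression)
      if (is.null(cfg$contrasts)) stop("contrasts required with expression input")
      res <- contrast_matrix(expr, cfg$contrasts, cfg$lfc_threshold)
      cl <- tryCatch(cluster_genes(expr), error = function(e) NULL)
      list(results = res, counts = direction_counts(res), clusters = cl)
    })
    paths$contrasts <- file.path(cfg$out_dir, "contrasts.tsv")
    write_tsv(expr_out$results, paths$contrasts)
    paths$direction_counts <- file.path(cfg$out_dir, "direction_counts.tsv")
    write_tsv(expr_out$counts, paths$direction_counts)
    if (!is.null(expr_out$clusters)) {
      paths$cluster_order <- file.path(cfg$out_dir, "cluster_order.txt")
      writeLines(expr_out$clusters$order, paths$cluster_order)
    }
  }

  ct_out <- NULL
  if (!is.null(cfg$ct)) {
    ct_out <- stage("qpcr", {
      ct <- read_ct_table(cfg$ct)
      if (is.null(cfg$ct_target) || is.null(cfg$ct_calibrator))
        stop("ct_target and ct_calibrator required with Ct input")
      ddct(ct, cfg$ct_target, cfg$ct_reference, cfg$ct_calibrator)
    })
    paths$ddct <- file.path(cfg$out_dir, "ddct.tsv")
    write_tsv(ct_out, paths$ddct)
  }

  paths$config <- file.path(cfg$out_dir, "config.json")
  jsonlite::write_json(cfg[!vapply(cfg, is.null, logical(1L))],
                       paths$config, auto_unbox = TRUE, null = "null")
  paths$log <- file.path(cfg$out_dir, "run_log.txt")
  writeLines(log_lines, paths$log)

  invisible(list(records = records, assignments = assignments,
                 domains = domains, motifs = motifs, expression = expr_out,
                 ddct = ct_out, tree = tree, paths = paths))
}
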