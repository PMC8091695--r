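#' Pipeline configuration
#'
#' Collects the input paths and all analysis thresholds with their
#' standard defaults: promoter window -2000/+100, proximal promoter
#' -1000/+100, 5000 enrichment permutations, adjusted-p 0.05 and
#' |log2FC| > 1 for DPI/DEG calls, FPKM > 1 in >= 3 samples for the
#' expression filter, FPKM bins at 2/5/10/30, 6 expression clusters,
#' 100 bp motif half-window and motif alpha 0.01.
#'
#' @param chrom_sizes,gtf,fasta,meme Input file paths.
#' @param peaks Named list: stage -> character vector of replicate
#'   peak files (narrowPeak).
#' @param peak_counts,gene_counts,samples Count matrix / sample sheet
#'   paths.
#' @param promoter_upstream,promoter_downstream,proximal_upstream,proximal_downstream
#'   Annotation windows (bp).
#' @param n_perm Enrichment permutations.
#' @param alpha,lfc_min Differential-call thresholds.
#' @param fpkm_min,min_samples Expression-filter thresholds.
#' @param k Number of expression clusters.
#' @param motif_halfwidth,motif_alpha Motif stage parameters.
#' @param seed RNG seed for the stochastic stages.
#' @param stage_order Stage labels in developmental order.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(chrom_sizes, gtf, peaks,
                            peak_counts = NULL, gene_counts = NULL,
                            samples = NULL, fasta = NULL, meme = NULL,
                            promoter_upstream = 2000,
                            promoter_downstream = 100,
                            proximal_upstream = 1000,
                            proximal_downstream = 100,
                            n_perm = 5000, alpha = 0.05, lfc_min = 1,
                            fpkm_min = 1, min_samples = 3, k = 6,
                            motif_halfwidth = 100, motif_alpha = 0.01,
                            seed = 1L, stage_order = names(peaks)) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; unknown
#' keys are rejected.
#'
#' @param path YAML file path.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' Write the resolved configuration into the run directory
#'
#' @param config A `pipeline_config`.
#' @param path Output YAML path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

check_inputs <- function(config, fields) {
  for (f in fields) {
    p <- config[[f]]
    if (is.null(p)) stop("config field '", f, "' is required here")
    paths <- unlist(p, use.names = FALSE)
    miss <- paths[!file.exists(paths)]
    if (length(miss)) stop("missing input file: ", miss[1L])
  }
}

#' Run pipeline stages
#'
#' Executes the named stage (or `all`) against the inputs in `config`,
#' writing plain TSV/BED artifacts under `outdir` and returning the
#' in-memory results invisibly.  Stages: `consensus`, `annotate`,
#' `enrich`, `partition`, `dpi`, `deg`, `integrate`, `cluster`,
#' `motif`, `report`.  Re-running with an identical config, inputs and
#' seed reproduces the outputs.
#'
#' @param config A [pipeline_config()].
#' @param outdir Run directory (created).
#' @param stages Character vector of stage names, or "all".
#' @return Invisibly, a named list of per-stage results.
#' @export
run_pipeline <- function(config, outdir, stages = "all") {
  all_stages <- c("consensus", "annotate", "enrich", "partition",
                  "dpi", "deg", "integrate", "cluster", "motif",
                  "report")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage: ", bad[1L])
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_pipeline_config(config, file.path(outdir, "config_resolved.yaml"))
  set.seed(config$seed)
  state <- new.env(parent = emptyenv())
  for (s in stages) {
    message("[acrstage] stage: ", s)
    switch(s,
           consensus = stage_consensus(config, outdir, state),
           annotate = stage_annotate(config, outdir, state),
           enrich = stage_enrich(config, outdir, state),
           partition = stage_partition_run(config, outdir, state),
           dpi = stage_dpi(config, outdir, state),
           deg = stage_deg(config, outdir, state),
           integrate = stage_integrate(config, outdir, state),
           cluster = stage_cluster(config, outdir, state),
           motif = stage_motif(config, outdir, state),
           report = stage_report(config, outdir, state))
  }
  invisible(as.list(state))
}

need <- function(state, what, config, outdir) {
  if (!exists(what, envir = state)) {
    runner <- switch(what,
                     consensus = stage_consensus,
                     annotated = stage_annotate,
                     partition = stage_partition_run,
                     dpi = stage_dpi,
                     deg = stage_deg,
                     integrate = stage_integrate,
                     cluster = stage_cluster)
    runner(config, outdir, state)
  }
  get(what, envir = state)
}

load_models <- function(config, state) {
  if (!exists("models", envir = state)) {
    check_inputs(config, c("chrom_sizes", "gtf"))
    cs <- read_chrom_sizes(config$chrom_sizes)
    state$chrom_sizes <- cs
    state$models <- read_gene_models(config$gtf, cs)
    state$ann_config <- annotation_config(
      promoter_upstream = config$promoter_upstream,
      promoter_downstream = config$promoter_downstream,
      proximal_upstream = config$proximal_upstream,
      proximal_downstream = config$proximal_downstream)
  }
  state$models
}

stage_consensus <- function(config, outdir, state) {
  check_inputs(config, c("chrom_sizes", "peaks"))
  cs <- read_chrom_sizes(config$chrom_sizes)
  state$chrom_sizes <- cs
  cons <- lapply(config$stage_order, function(st) {
    reps <- lapply(config$peaks[[st]], read_peaks, dialect = "narrowPeak",
                   chrom_sizes = cs)
    consensus_peaks(reps, label = st)
  })
  names(cons) <- config$stage_order
  for (st in names(cons))
    write_peaks(cons[[st]], file.path(outdir,
                                      paste0("consensus_", st, ".bed")),
                dialect = "BED6")
  cov <- vapply(cons, genome_coverage, numeric(1), chrom_sizes = cs)
  summary <- data.frame(stage = names(cons),
                        n_peaks = vapply(cons, length, integer(1)),
                        genome_coverage = as.numeric(cov))
  write.table(summary, file.path(outdir, "consensus_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  counts <- lapply(cons, chrom_peak_counts, chrom_sizes = cs)
  write.table(data.frame(chrom = names(cs), do.call(cbind, counts)),
              file.path(outdir, "chrom_peak_counts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  state$consensus <- cons
  state$consensus_summary <- summary
}

stage_annotate <- function(config, outdir, state) {
  cons <- need(state, "consensus", config, outdir)
  models <- load_models(config, state)
  ann <- lapply(cons, annotate_peaks, models = models,
                config = state$ann_config)
  for (st in names(ann))
    write_annotated_peaks(ann[[st]],
                          file.path(outdir, paste0("annotated_", st,
                                                   ".bed")))
  classes <- do.call(rbind, lapply(names(ann), function(st)
    cbind(stage = st, feature_class_table(ann[[st]]))))
  write.table(classes, file.path(outdir, "feature_classes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  state$annotated <- ann
  state$feature_classes <- classes
}

stage_enrich <- function(config, outdir, state) {
  cons <- need(state, "consensus", config, outdir)
  models <- load_models(config, state)
  enr <- lapply(names(cons), function(st)
    cbind(stage = st,
          fold_enrichment(cons[[st]], models, state$chrom_sizes,
                          n_perm = config$n_perm,
                          config = state$ann_config)))
  enr <- do.call(rbind, enr)
  write.table(enr, file.path(outdir, "fold_enrichment.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  ncl <- lapply(names(cons), function(st) {
    nl <- normalized_chrom_lengths(state$chrom_sizes, length(cons[[st]]))
    cc <- chrom_correlation(nl, chrom_peak_counts(cons[[st]],
                                                  state$chrom_sizes))
    data.frame(stage = st, r = cc$r, r_squared = cc$r_squared)
  })
  ncl <- do.call(rbind, ncl)
  write.table(ncl, file.path(outdir, "chrom_correlation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  state$enrichment <- enr
  state$chrom_corr <- ncl
}

stage_partition_run <- function(config, outdir, state) {
  cons <- need(state, "consensus", config, outdir)
  part <- stage_partition(cons)
  for (st in names(part$specific))
    write_peaks(part$specific[[st]],
                file.path(outdir, paste0("specific_", st, ".bed")),
                dialect = "BED6")
  write_peaks(part$common, file.path(outdir, "common.bed"),
              dialect = "BED6")
  write.table(part$counts, file.path(outdir, "partition_counts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  state$partition <- part
}

read_config_counts <- function(config, which) {
  check_inputs(config, c(which, "samples"))
  read_count_matrix(config[[which]], config$samples)
}

pairwise_contrasts <- function(stage_order) {
  n <- length(stage_order)
  out <- list()
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n)
    out[[length(out) + 1L]] <- c(stage_order[b], stage_order[a])
  out
}

run_differential <- function(cm, config, outdir, prefix) {
  contrasts <- pairwise_contrasts(config$stage_order)
  res <- lapply(contrasts, function(ct)
    nb_differential(cm$counts, cm$samples, ct,
                    alpha = config$alpha, lfc_min = config$lfc_min))
  names(res) <- vapply(contrasts, paste, "", collapse = "_vs_")
  for (nm in names(res))
    write_differential(res[[nm]],
                       file.path(outdir, paste0(prefix, "_", nm, ".tsv")))
  summ <- do.call(rbind, lapply(names(res), function(nm)
    data.frame(contrast = nm,
               t(significance_summary(res[[nm]], config$alpha,
                                      config$lfc_min)))))
  write.table(summ, file.path(outdir, paste0(prefix, "_summary.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  list(records = res, summary = summ)
}

stage_dpi <- function(config, outdir, state) {
  cm <- read_config_counts(config, "peak_counts")
  state$dpi <- run_differential(cm, config, outdir, "dpi")
  state$peak_cm <- cm
}

stage_deg <- function(config, outdir, state) {
  cm <- read_config_counts(config, "gene_counts")
  models <- load_models(config, state)
  lens <- setNames(models$genes$exonic_length, models$genes$gene_id)
  libs <- if (!is.null(cm$samples$library_size))
    setNames(cm$samples$library_size, cm$samples$sample_id)[
      colnames(cm$counts)] else colSums(cm$counts)
  expr <- fpkm(cm$counts, lens, libs)
  expressed <- filter_expressed(expr, cm$samples,
                                min_fpkm = config$fpkm_min,
                                min_samples = config$min_samples)
  diff <- run_differential(
    list(counts = cm$counts[expressed, , drop = FALSE],
         samples = cm$samples), config, outdir, "deg")
  degs <- unique(unlist(lapply(diff$records, function(r)
    r$feature_id[r$direction != "ns"])))
  writeLines(degs, file.path(outdir, "deg_ids.txt"))
  state$gene_cm <- cm
  state$expr <- expr
  state$expressed <- expressed
  state$deg <- c(diff, list(deg_ids = degs))
}

stage_integrate <- function(config, outdir, state) {
  ann <- need(state, "annotated", config, outdir)
  if (!exists("expr", envir = state)) stage_deg(config, outdir, state)
  acr_maps <- lapply(ann, map_promoter_acrs)
  tabs <- list()
  for (st in names(acr_maps)) {
    cols <- state$gene_cm$samples$sample_id[
      state$gene_cm$samples$stage == st]
    stage_mean <- rowMeans(state$expr[, cols, drop = FALSE])
    for (stat in c("single", "max", "total")) {
      lens <- acr_length_statistic(acr_maps[[st]], stat)
      lens <- lens[names(lens) %in% rownames(state$expr)]
      if (length(lens) < 3L) next
      grp <- assign_length_groups(lens, stat)
      bins <- bin_expression(stage_mean[grp$gene_id])
      names(bins) <- grp$gene_id
      tab <- group_bin_table(setNames(grp$group, grp$gene_id), bins)
      tabs[[paste(st, stat, sep = "_")]] <- tab
      write.table(data.frame(group = rownames(tab), tab,
                             check.names = FALSE),
                  file.path(outdir, sprintf("group_bins_%s_%s.tsv",
                                            st, stat)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  state$acr_maps <- acr_maps
  state$group_bins <- tabs
}

stage_cluster <- function(config, outdir, state) {
  if (!exists("deg", envir = state)) stage_deg(config, outdir, state)
  degs <- state$deg$deg_ids
  if (length(degs) < config$k)
    stop("fewer DEGs than clusters")
  cl <- cluster_degs(state$expr[degs, , drop = FALSE],
                     state$gene_cm$samples, k = config$k)
  write.table(data.frame(gene_id = names(cl$clusters),
                         cluster = unname(cl$clusters)),
              file.path(outdir, "deg_clusters.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  state$clusters <- cl
}

stage_motif <- function(config, outdir, state) {
  check_inputs(config, c("fasta", "meme"))
  part <- need(state, "partition", config, outdir)
  pwms <- read_meme_pwms(config$meme)
  fa <- Biostrings::readDNAStringSet(config$fasta)
  target <- centered_windows(part$specific[[1L]],
                             halfwidth = config$motif_halfwidth)
  background <- centered_windows(part$common,
                                 halfwidth = config$motif_halfwidth)
  enr <- motif_enrichment(extract_sequences(target, fa),
                          extract_sequences(background, fa),
                          pwms, alpha = config$motif_alpha)
  write.table(enr, file.path(outdir, "motif_enrichment.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  state$motifs <- enr
}

stage_report <- function(config, outdir, state) {
  parts <- list()
  if (exists("consensus_summary", envir = state))
    parts$consensus <- state$consensus_summary
  if (exists("feature_classes", envir = state))
    parts$classes <- state$feature_classes
  if (exists("partition", envir = state))
    parts$partition <- state$partition$counts
  if (exists("dpi", envir = state)) parts$dpi <- state$dpi$summary
  if (exists("deg", envir = state)) parts$deg <- state$deg$summary
  if (length(parts) == 0L)
    stop("nothing to report: run analysis stages first")
  lines <- character()
  for (nm in names(parts)) {
    lines <- c(lines, paste0("# ", nm),
               utils::capture.output(print(parts[[nm]],
                                           row.names = FALSE)), "")
  }
  writeLines(lines, file.path(outdir, "report.txt"))
  state$report <- parts
}
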