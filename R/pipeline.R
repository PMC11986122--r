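#' Run the full analysis pipeline from a config
#'
#' Orchestrates simulate -> network -> cluster -> sharing -> ne ->
#' validate -> surnames -> classify -> pca from one YAML config (or an
#' equivalent list), writing plain TSV results plus a machine-readable
#' `manifest.yaml` (config hash, seeds, per-stage row counts, versions) to
#' the output directory. Stages are toggled via `stages:`; each stochastic
#' stage reads its own integer seed from `seeds:`. Reruns with the same
#' config are bit-identical apart from nothing: no timestamps are written.
#'
#' Config keys (see `inst/extdata/demo_config.yaml` for a worked example):
#' `genome` (n_chrom, total_cM), `demography` (populations, splits,
#' ancestral, G_max, m_cM), `samples_per_pop`, `seeds`, `stages`,
#' `network` (min_segment_cM, max_total_cM), `leiden` (levels,
#' resolutions, min_size), `sharing` (level, n_boot), `ne` (lambda),
#' `validate` (level, n_perm, n_boot), `surnames` (origins, enrichment),
#' `classify` (level, fraction), `pca` (reference_pops, bin).
#'
#' @param config path to a YAML file, or a list with the same structure.
#' @param outdir output directory (created if missing).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) {
    cfg_path <- config
    cfg <- yaml::read_yaml(config)
  } else {
    cfg <- config
    cfg_path <- NULL
  }
  validate_config(cfg)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(cfg_path)) {
    cfg_path <- file.path(outdir, "config.yaml")
    yaml::write_yaml(cfg, cfg_path)
  }
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_path)),
    package_version = as.character(utils::packageVersion("ibdscape")),
    seeds = cfg$seeds, rows = list())
  stage_on <- function(s) isTRUE(cfg$stages[[s]])
  note <- function(...) message("[ibdscape] ", ...)

  genome <- if (is.null(cfg$genome)) default_genome()
            else default_genome(cfg$genome$n_chrom, cfg$genome$total_cM)
  segments <- roh <- meta <- assignment <- NULL

  if (stage_on("simulate")) {
    note("simulate: drawing IBD/ROH segments and genotypes")
    model <- config_demography(cfg$demography)
    spp <- unlist(cfg$samples_per_pop)
    segments <- simulate_ibd(model, spp, genome, cfg$seeds$simulate)
    roh <- simulate_roh(model, spp, genome, cfg$seeds$simulate + 1)
    write_segments(segments, file.path(outdir, "segments.ibd"))
    write_segments(roh, file.path(outdir, "segments.hbd"))
    manifest$rows$segments_ibd <- nrow(segments)
    manifest$rows$segments_hbd <- nrow(roh)
  }

  if (stage_on("network")) {
    note("network: building and filtering the sharing network")
    segments <- segments %||% read_segments(file.path(outdir, "segments.ibd"))
    net <- build_network(segments, cfg$network$min_segment_cM %||% 4)
    filt <- filter_relatives(net, cfg$network$max_total_cM %||% 1400)
    utils::write.table(filt$network$edges, file.path(outdir, "network.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$rows$network_edges <- nrow(filt$network$edges)
    manifest$rows$removed_relatives <- length(filt$removed)

    lei <- cfg$leiden %||% list()
    assignment <- recursive_leiden(
      filt$network, levels = lei$levels %||% 3,
      resolutions = unlist(lei$resolutions) %||% rep(1, lei$levels %||% 3),
      min_size = lei$min_size %||% 30, seed = cfg$seeds$cluster)
    utils::write.table(assignment, file.path(outdir, "communities.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$rows$communities <-
      length(unique(assignment[[paste0("level", lei$levels %||% 3)]]))
  }

  if (stage_on("sharing")) {
    note("sharing: time-stratified community summaries")
    lev <- cfg$sharing$level %||% "level1"
    sm <- pairwise_sharing(segments, assignment, level = lev,
                           n_boot = cfg$sharing$n_boot %||% 200,
                           seed = cfg$seeds$sharing)
    utils::write.table(sm, file.path(outdir, "sharing.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest$rows$sharing <- nrow(sm)
    if (!is.null(roh)) {
      fr <- f_roh(roh, genome, samples = assignment$sample_id)
      utils::write.table(
        data.frame(sample_id = names(fr), f_roh = fr),
        file.path(outdir, "froh.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      manifest$rows$froh <- length(fr)
    }
  }

  if (stage_on("ne")) {
    note("ne: fitting effective-population-size trajectories per community")
    lev <- cfg$ne$level %||% "level1"
    rows <- list()
    for (cm in sort(unique(assignment[[lev]]))) {
      ids <- assignment$sample_id[assignment[[lev]] == cm]
      if (length(ids) < 5) next
      sp <- count_spectrum(segments, ids)
      fit <- tryCatch(
        fit_piecewise_ne(sp$k, sp$P, genome = genome,
                         lambda = cfg$ne$lambda %||% 1,
                         seed = cfg$seeds$ne),
        error = function(e) NULL)
      if (is.null(fit)) next
      rows[[cm]] <- cbind(community = cm, fit$epochs)
    }
    ne_tab <- do.call(rbind, rows)
    utils::write.table(ne_tab, file.path(outdir, "ne.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest$rows$ne <- if (is.null(ne_tab)) 0 else nrow(ne_tab)
  }

  if (stage_on("validate")) {
    note("validate: TVD permutation tests and bootstrap dendrogram")
    lev <- cfg$validate$level %||% "level1"
    prof <- sample_profiles(segments, assignment, level = lev)
    lab <- stats::setNames(assignment[[lev]], assignment$sample_id)
    comms <- sort(unique(lab))
    rows <- list()
    if (length(comms) >= 2) {
      for (i in seq_along(comms)) for (j in seq_along(comms)) {
        if (j <= i) next
        a <- names(lab)[lab == comms[i]]; b <- names(lab)[lab == comms[j]]
        tv <- tryCatch(tvd_permutation_test(
          prof, a, b, n_perm = cfg$validate$n_perm %||% 199,
          seed = cfg$seeds$validate,
          exclude_communities = c(comms[i], comms[j])),
          error = function(e) NULL)
        if (!is.null(tv))
          rows[[paste(i, j)]] <- data.frame(
            community_a = comms[i], community_b = comms[j],
            tvd = tv$tvd_obs, p = tv$p.value)
      }
    }
    tv_tab <- do.call(rbind, rows)
    utils::write.table(tv_tab, file.path(outdir, "tvd_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$rows$tvd_tests <- if (is.null(tv_tab)) 0 else nrow(tv_tab)
    if (length(comms) >= 3) {
      cp <- do.call(rbind, lapply(comms, function(cm)
        colMeans(prof[names(lab)[lab == cm], , drop = FALSE])))
      rownames(cp) <- comms
      dd <- bootstrap_dendrogram(cp, n_boot = cfg$validate$n_boot %||% 200,
                                 seed = cfg$seeds$validate)
      writeLines(dd$newick, file.path(outdir, "dendrogram.nwk"))
      manifest$rows$dendrogram_branches <- length(dd$supports)
    }
  }

  if (stage_on("surnames")) {
    note("surnames: origin enrichment within communities")
    lev <- cfg$surnames$level %||% "level1"
    lab <- stats::setNames(assignment[[lev]], assignment$sample_id)
    em <- do.call(rbind, lapply(cfg$surnames$enrichment, unlist))
    comms <- sort(unique(lab))
    # recycle the configured enrichment rows over the detected communities
    em <- em[(seq_along(comms) - 1) %% nrow(em) + 1, , drop = FALSE]
    rownames(em) <- comms
    meta <- simulate_surnames(lab, cfg$surnames$origins, em,
                              cfg$seeds$surnames)
    write_metadata(meta, file.path(outdir, "metadata.tsv"))
    tab <- build_table(meta, assignment, level = lev)
    omni <- chi2_test(tab)
    cells <- enrichment_cells(tab)
    out <- rbind(
      data.frame(origin = "(omnibus)", community = "(all)",
                 observed = sum(tab), expected = sum(tab),
                 residual = omni$chi2, p = omni$p.value,
                 p_adj = omni$p.value,
                 direction = sprintf("V_adj=%.3f", cramers_v(tab))),
      cells)
    utils::write.table(out, file.path(outdir, "surnames.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest$rows$surname_cells <- nrow(cells)
  }

  if (stage_on("classify")) {
    note("classify: naive Bayes regional-ancestry model")
    lev <- cfg$classify$level %||% "level2"
    lab <- stats::setNames(assignment[[lev]], assignment$sample_id)
    # keep classes large enough that the training split holds >= 5 each
    frac <- cfg$classify$fraction %||% 0.8
    big <- names(which(table(lab) >= ceiling(5 / frac) + 1))
    if (length(big) < 2) stop("classify: fewer than 2 usable classes")
    lab <- lab[lab %in% big]
    feats <- feature_matrix(segments, assignment, names(lab), level = lev)
    sp <- stratified_split(unname(lab), cfg$classify$fraction %||% 0.8,
                           seed = cfg$seeds$classify)
    model <- nb_train(feats[sp$train, , drop = FALSE],
                      unname(lab)[sp$train])
    ev <- nb_evaluate(model, feats[sp$validation, , drop = FALSE],
                      unname(lab)[sp$validation])
    pred <- nb_predict(model, feats[sp$validation, , drop = FALSE])
    utils::write.table(pred, file.path(outdir, "predictions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$rows$validation_samples <- length(sp$validation)
    manifest$rows$validation_accuracy <- ev$accuracy
  }

  if (stage_on("pca")) {
    note("pca: European-affinity biplot per bin")
    refs <- unlist(cfg$pca$reference_pops)
    lev <- cfg$pca$level %||% "level1"
    pop_of <- sub("_.*$", "", assignment$sample_id)
    tgt <- assignment[!pop_of %in% refs, , drop = FALSE]
    ref <- data.frame(sample_id = assignment$sample_id[pop_of %in% refs],
                      level1 = pop_of[pop_of %in% refs])
    bin <- unlist(cfg$pca$bin) %||% c(1, 3)
    if (length(bin) == 1) bin <- c(bin, Inf)
    am <- affinity_matrix(segments, tgt, ref, bin,
                          target_level = lev, reference_level = "level1")
    bp <- pca_biplot(am)
    utils::write.table(
      data.frame(community = rownames(bp$scores), bp$scores),
      file.path(outdir, "pca_scores.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(
      data.frame(reference = rownames(bp$loadings), bp$loadings),
      file.path(outdir, "pca_loadings.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    manifest$rows$pca_var_pc1 <- bp$var_explained[1]
  }

  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(manifest)
}

validate_config <- function(cfg) {
  if (!is.list(cfg) || is.null(cfg$stages) || is.null(cfg$seeds))
    stop("config must define 'stages' and 'seeds'")
  on <- names(Filter(isTRUE, cfg$stages))
  need_seed <- intersect(on, c("simulate", "cluster", "sharing", "ne",
                               "validate", "surnames", "classify"))
  need_seed <- sub("^network$", "cluster", need_seed)
  miss <- setdiff(need_seed, names(cfg$seeds))
  if ("network" %in% on && is.null(cfg$seeds$cluster))
    miss <- union(miss, "cluster")
  if (length(miss) > 0)
    stop("missing seed(s) for stage(s): ", paste(miss, collapse = ", "))
  if ("simulate" %in% on &&
      (is.null(cfg$demography) || is.null(cfg$samples_per_pop)))
    stop("simulate stage needs 'demography' and 'samples_per_pop'")
  downstream <- setdiff(on, "simulate")
  if (length(downstream) > 0 && !"simulate" %in% on &&
      is.null(cfg$paths$segments))
    stop("downstream stages need either the simulate stage or paths$segments")
  invisible(cfg)
}

config_demography <- function(d) {
  pops <- lapply(d$populations, function(p) {
    if (is.list(p)) do.call(rbind.data.frame, p) else p
  })
  splits <- if (!is.null(d$splits))
    do.call(rbind.data.frame, d$splits)
  anc <- if (is.list(d$ancestral)) do.call(rbind.data.frame, d$ancestral)
         else d$ancestral
  demography_model(pops, splits, anc,
                   G_max = d$G_max %||% 300, m_cM = d$m_cM %||% 1.0)
}
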