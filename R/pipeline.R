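#' Default pipeline configuration
#'
#' Returns the full default configuration for [run_pipeline()]: synthetic
#' fixture parameters for every stage plus the analysis parameters (VISTA
#' window and threshold, motif set, fold-change and significance thresholds,
#' OR-linkage distance). Any element can be overridden by the `config`
#' argument of [run_pipeline()].
#'
#' @param seed Global seed; per-stage substreams are derived from it.
#' @return A nested list.
#' @export
default_pipeline_config <- function(seed = 1) {
  list(
    seed = seed,
    panel = list(n_elements = 36, n_syntenic_all = 21, n_or_linked = 15,
                 element_length = 2000, substitution_rate = 0.15,
                 indel_rate = 0.01),
    conserve = list(max_distance = 1e6),
    vista = list(window = 100, threshold_pct = 70, min_width = 100,
                 region_length = 5000, island = c(1500, 2200),
                 background_rate = 0.4, island_rate = 0.02),
    motifs = list(background_length = 2000, core_window = 430,
                  placements = tibble(
                    motif_name = c("class1_specific", "homeodomain",
                                   "extended_homeodomain", "homeodomain",
                                   "oe_like", "homeodomain"),
                    position = c(1010, 1060, 1110, 1170, 1250, 1330),
                    strand = c("+", "+", "+", "-", "+", "-"))),
    expression = list(n_genes = 200, n_replicates_per_group = 6,
                      max_knockdown_log2 = 2, noise_sd_log2 = 0.3,
                      fc_threshold = 1.3, alpha = 0.05, moderated = FALSE),
    cellcounts = list(group_means = c(148, 306), group_sds = c(33.8, 97.3),
                      ns = c(6, 5), group_names = c("intact", "deleted")))
}

modify_list <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(base[[nm]]) && is.list(new[[nm]]) && !is.data.frame(new[[nm]])) {
      base[[nm]] <- modify_list(base[[nm]], new[[nm]])
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}

#' Run the full analysis pipeline on synthetic fixtures
#'
#' Orchestrates every stage in dependency order: fixture simulation,
#' conservation scoring with the all-species synteny filter and OR-gene
#' linkage, element ranking, VISTA-style identity profiling with conserved
#' segment calling, motif scanning with core-window detection, the
#' differential-expression analysis, and the cell-count statistics.
#' All outputs are written as TSV/JSON under `out_dir` along with the
#' effective configuration; reruns with the same config and seed are
#' byte-identical.
#'
#' @param config Optional list or path to a YAML file overriding parts of
#'   [default_pipeline_config()].
#' @param out_dir Output directory (default a fresh temporary directory).
#' @param stages Stages to run, in dependency order; default all.
#' @return A report list with per-stage headline results and output paths,
#'   invisibly.
#' @export
run_pipeline <- function(config = NULL, out_dir = tempfile("orenhancer_run_"),
                         stages = c("simulate", "conserve", "vista", "motifs",
                                    "de", "stats")) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  cfg <- default_pipeline_config()
  if (!is.null(config)) cfg <- modify_list(cfg, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(purrr::map(cfg, function(x) {
    if (is.data.frame(x)) as.list(x) else x
  }), file.path(out_dir, "effective_config.yaml"))
  report <- list(seed = cfg$seed, out_dir = out_dir)
  elapsed <- function(t0) round(as.numeric(Sys.time()) - t0, 2)

  run_stage <- function(name, fn) {
    t0 <- as.numeric(Sys.time())
    message(sprintf("[%s] starting", name))
    res <- tryCatch(fn(), error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
    message(sprintf("[%s] done in %ss", name, elapsed(t0)))
    res
  }

  panel <- NULL
  if ("simulate" %in% stages || "conserve" %in% stages) {
    panel <- run_stage("simulate", function() {
      do.call(simulate_enhancer_panel,
              c(cfg$panel, list(seed = substream_seed(cfg$seed, 1),
                                dir = file.path(out_dir, "fixtures"))))
    })
    report$simulate <- list(n_elements = nrow(panel$elements),
                            n_species = length(panel$species))
  }

  if ("conserve" %in% stages) {
    cons <- run_stage("conserve", function() {
      records <- score_conservation(panel$elements, panel$alignments)
      retained <- filter_all_species(records, panel$species)
      linkage <- link_nearest_or(
        records[records$element_id %in% retained & records$syntenic_found, ],
        panel$or_genes, max_distance = cfg$conserve$max_distance)
      linked_all <- dplyr::summarise(dplyr::group_by(linkage, .data$element_id),
                                     linked_all = all(.data$linked))
      final <- sort(linked_all$element_id[linked_all$linked_all])
      ranking <- rank_elements(records, element_ids = final)
      list(records = records, retained = retained, linkage = linkage,
           final = final, ranking = ranking)
    })
    readr::write_tsv(cons$records, file.path(out_dir, "conservation_records.tsv"))
    readr::write_tsv(cons$linkage, file.path(out_dir, "or_linkage.tsv"))
    readr::write_tsv(cons$ranking, file.path(out_dir, "conservation_ranking.tsv"))
    report$conserve <- list(n_candidates = nrow(panel$elements),
                            n_syntenic_all = length(cons$retained),
                            n_or_linked = length(cons$final),
                            top_element = cons$ranking$element_id[1],
                            top_mean_index = cons$ranking$mean_index[1])
  }

  if ("vista" %in% stages) {
    v <- run_stage("vista", function() {
      vc <- cfg$vista
      n <- vc$region_length
      sim_bg <- simulate_pairwise_alignment(
        length = n, substitution_rate = vc$background_rate,
        seed = substream_seed(cfg$seed, 2), ref_chrom = "chrV")
      # overwrite the island with a near-identical stretch
      rr <- str_chars(sim_bg$blocks$ref_row)
      qr <- str_chars(sim_bg$blocks$query_row)
      isl <- seq(vc$island[1] + 1, vc$island[2])
      island_sim <- simulate_pairwise_alignment(
        length = length(isl), substitution_rate = vc$island_rate,
        seed = substream_seed(cfg$seed, 3))
      rr[isl] <- str_chars(island_sim$blocks$ref_row)
      qr[isl] <- str_chars(island_sim$blocks$query_row)
      blocks <- sim_bg$blocks
      blocks$ref_row <- paste(rr, collapse = "")
      blocks$query_row <- paste(qr, collapse = "")
      region <- genomic_interval("chrV", 0, n)
      prof <- windowed_identity(blocks, region, window = vc$window)
      segs <- call_conserved_segments(prof, threshold_pct = vc$threshold_pct,
                                      min_width = vc$min_width)
      list(profile = prof, segments = segs)
    })
    readr::write_tsv(as_tibble(v$profile), file.path(out_dir, "identity_profile.tsv"))
    if (nrow(v$segments) > 0) {
      write_bed(dplyr::mutate(v$segments, name = "conserved",
                              score = round(.data$mean_identity_pct, 1),
                              strand = "*"),
                file.path(out_dir, "conserved_segments.bed"))
    }
    report$vista <- list(n_segments = nrow(v$segments),
                         segment_spans = if (nrow(v$segments)) paste(
                           sprintf("%.0f-%.0f", v$segments$start, v$segments$end),
                           collapse = ",") else "")
  }

  if ("motifs" %in% stages) {
    mo <- run_stage("motifs", function() {
      mc <- cfg$motifs
      placements <- as_tibble(mc$placements)
      fix <- embed_motifs(mc$background_length, placements = placements,
                          seed = substream_seed(cfg$seed, 4))
      hits <- iupac_scan(fix$sequence)
      core <- find_core_window(hits, nchar(fix$sequence),
                               window = mc$core_window)
      list(fixture = fix, hits = hits, core = core)
    })
    readr::write_tsv(mo$hits, file.path(out_dir, "motif_hits.tsv"))
    core_summary <- if (is.null(mo$core)) list(found = FALSE) else
      list(found = TRUE, start = mo$core$interval$start,
           end = mo$core$interval$end, n_hits = nrow(mo$core$hits),
           n_classes = length(unique(mo$core$hits$motif_name)))
    jsonlite::write_json(core_summary, file.path(out_dir, "core_window.json"),
                         auto_unbox = TRUE, digits = NA)
    report$motifs <- c(list(n_hits = nrow(mo$hits)), core_summary)
  }

  if ("de" %in% stages) {
    de <- run_stage("de", function() {
      ec <- cfg$expression
      sim <- simulate_cluster_expression(
        n_genes = ec$n_genes, n_replicates_per_group = ec$n_replicates_per_group,
        max_knockdown_log2 = ec$max_knockdown_log2,
        noise_sd_log2 = ec$noise_sd_log2,
        seed = substream_seed(cfg$seed, 5),
        dir = file.path(out_dir, "fixtures"))
      res <- de_analyze(sim$intensities, sim$groups, sim$genes, sim$element,
                        moderated = ec$moderated,
                        fc_threshold = ec$fc_threshold, alpha = ec$alpha)
      list(sim = sim, res = res)
    })
    readr::write_tsv(tidy(de$res), file.path(out_dir, "de_calls.tsv"))
    gl <- glance(de$res)
    jsonlite::write_json(as.list(gl), file.path(out_dir, "de_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    report$de <- c(as.list(gl), list(expected_r = de$sim$expected_r))
  }

  if ("stats" %in% stages) {
    st <- run_stage("stats", function() {
      cc <- cfg$cellcounts
      counts <- simulate_cell_counts(cc$group_means, cc$group_sds, cc$ns,
                                     group_names = cc$group_names,
                                     seed = substream_seed(cfg$seed, 6))
      g <- split(counts$value, counts$group)[cc$group_names]
      tt <- t_from_raw(g[[1]], g[[2]])
      list(counts = counts, t = tt)
    })
    readr::write_tsv(st$counts, file.path(out_dir, "cell_counts.tsv"))
    jsonlite::write_json(as.list(st$t), file.path(out_dir, "cellcount_ttest.json"),
                         auto_unbox = TRUE, digits = NA)
    report$stats <- list(t = st$t$t, df = st$t$df, p = st$t$p)
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
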