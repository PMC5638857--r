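#' Simulate a pairwise alignment of an element with known truth
#'
#' Generates a random reference element and a diverged query: substitutions
#' are drawn per site with the given rate, uniformly over the three
#' alternative bases (so the expected identity is `1 - substitution_rate`);
#' indels occur per site with the given rate, split evenly between deletions
#' (reference bases opposite query gaps) and insertions (query-only bases),
#' with geometric lengths of the stated mean. The realized truth —
#' `true_coverage` (aligned reference sites / length) and `true_identity`
#' (matching columns / aligned columns) — is computed by construction, never
#' by the conservation code under test. `dropout = TRUE` emulates an element
#' absent from a species and yields an empty block set.
#'
#' @param length Element length in bp.
#' @param substitution_rate,indel_rate Per-site rates in `[0, 1]`.
#' @param mean_indel_length Mean indel length in bp (geometric).
#' @param dropout Element absent from this species.
#' @param seed Integer seed; identical seeds give identical output.
#' @param ref_chrom,ref_start Reference anchor of the element.
#' @param query_chrom,query_start Query anchor of the aligned region.
#' @return List with `blocks` (alignment-block tibble, empty under dropout)
#'   and `truth` (list with `true_coverage`, `true_identity`).
#' @export
simulate_pairwise_alignment <- function(length, substitution_rate,
                                        indel_rate = 0, mean_indel_length = 3,
                                        dropout = FALSE, seed = 1,
                                        ref_chrom = "chrR", ref_start = 0,
                                        query_chrom = "chrQ", query_start = 0) {
  stopifnot(length > 0,
            substitution_rate >= 0, substitution_rate <= 1,
            indel_rate >= 0, indel_rate <= 1, mean_indel_length >= 1)
  if (dropout) {
    return(list(blocks = empty_blocks(),
                truth = list(true_coverage = 0, true_identity = NA_real_)))
  }
  withr::with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, length, replace = TRUE)
    sub <- runif(length) < substitution_rate
    qchar <- ref
    if (any(sub)) {
      qchar[sub] <- vapply(ref[sub], function(b) sample(setdiff(bases, b), 1),
                           character(1))
    }
    deleted <- rep(FALSE, length)
    ins_len <- rep(0L, length)
    ev <- which(runif(length) < indel_rate)
    for (i in ev) {
      g <- 1L + rgeom(1, prob = 1 / mean_indel_length)
      if (runif(1) < 0.5) {
        deleted[i:min(i + g - 1L, length)] <- TRUE
      } else {
        ins_len[i] <- ins_len[i] + g
      }
    }
    ref_pieces <- ref
    query_pieces <- ifelse(deleted, "-", qchar)
    for (i in which(ins_len > 0)) {
      ref_pieces[i] <- paste0(ref_pieces[i], strrep("-", ins_len[i]))
      query_pieces[i] <- paste0(query_pieces[i],
                                paste(sample(bases, ins_len[i], replace = TRUE),
                                      collapse = ""))
    }
    ref_row <- paste(ref_pieces, collapse = "")
    query_row <- paste(query_pieces, collapse = "")
    n_aligned <- sum(!deleted)
    qlen <- n_aligned + sum(ins_len)
    blocks <- tibble(ref_chrom = ref_chrom, ref_start = ref_start,
                     ref_end = ref_start + length,
                     query_chrom = query_chrom, query_start = query_start,
                     query_end = query_start + qlen,
                     query_strand = "+", score = 0,
                     ref_row = ref_row, query_row = query_row)
    validate_blocks(blocks)
    list(blocks = blocks,
         truth = list(true_coverage = n_aligned / length,
                      true_identity = if (n_aligned > 0)
                        sum(!deleted & !sub) / n_aligned else NA_real_))
  })
}

#' Simulate a multi-element, multi-species enhancer conservation screen
#'
#' Builds a panel of candidate elements on a reference chromosome together
#' with per-species pairwise alignments and OR-gene annotations, constructed
#' so that a designed number of elements have a syntenic region in every
#' species and a designed subset of those are linked to an OR gene within
#' the linkage distance in every species. The defaults mirror a screen of 36
#' candidate elements against 7 placental species in which 21 elements
#' survive the all-species synteny filter and 15 of those are OR-linked.
#' Element 1 is simulated with a lower substitution rate so that one element
#' is uniformly the most conserved.
#'
#' @param n_elements Number of candidate elements (default 36).
#' @param n_syntenic_all Elements with a syntenic region in all species
#'   (default 21); the rest drop out of at least one species.
#' @param n_or_linked Elements (among the syntenic ones) with an OR gene
#'   within `linked_distance` in every species (default 15); the others get
#'   their nearest OR at `unlinked_distance`.
#' @param species Character vector of species names (default 7 placentals).
#' @param element_length Element length in bp (default 2000).
#' @param substitution_rate,indel_rate,mean_indel_length Divergence
#'   parameters passed to [simulate_pairwise_alignment()].
#' @param top_substitution_rate Substitution rate for element 1.
#' @param linked_distance,unlinked_distance Gap between an element's aligned
#'   query span and its nearest OR gene for linked / unlinked elements.
#' @param seed Integer seed.
#' @param dir Optional output directory; when given, writes `elements.bed`,
#'   one AXT and one OR BED per species, and the truth tables as TSV.
#' @return List with `elements`, `alignments` (named list of block tibbles),
#'   `or_genes` (named list), `truth` (per-element tibble), `truth_records`
#'   (per element x species tibble) and, when `dir` is given, `files`.
#' @export
simulate_enhancer_panel <- function(n_elements = 36, n_syntenic_all = 21,
                                    n_or_linked = 15,
                                    species = c("human", "guinea_pig", "rabbit",
                                                "horse", "dog", "cow", "elephant"),
                                    element_length = 2000,
                                    substitution_rate = 0.15, indel_rate = 0.01,
                                    mean_indel_length = 3,
                                    top_substitution_rate = 0.05,
                                    linked_distance = 5e4,
                                    unlinked_distance = 1.5e6,
                                    seed = 1, dir = NULL) {
  stopifnot(n_elements >= 1, n_or_linked <= n_syntenic_all,
            n_syntenic_all <= n_elements)
  ids <- sprintf("elem_%02d", seq_len(n_elements))
  elements <- genomic_interval("chr7",
                               102e6 + (seq_len(n_elements) - 1) * 5e4,
                               102e6 + (seq_len(n_elements) - 1) * 5e4 + element_length,
                               name = ids)
  is_syntenic <- seq_len(n_elements) <= n_syntenic_all
  is_linked <- seq_len(n_elements) <= n_or_linked
  alignments <- list(); or_genes <- list()
  truth_records <- list()
  for (s in seq_along(species)) {
    sp <- species[s]
    blocks <- list(); genes <- list()
    for (i in seq_len(n_elements)) {
      # non-syntenic elements drop out of one species, cycling over species
      drop_here <- !is_syntenic[i] && ((i - 1) %% length(species)) + 1 == s
      rate <- if (i == 1) top_substitution_rate else substitution_rate
      qstart <- (i - 1) * 4e6 + 1e5
      sim <- simulate_pairwise_alignment(
        length = element_length, substitution_rate = rate,
        indel_rate = indel_rate, mean_indel_length = mean_indel_length,
        dropout = drop_here,
        seed = substream_seed(seed, s * 1000 + i),
        ref_chrom = "chr7", ref_start = elements$start[i],
        query_chrom = "syn1", query_start = qstart)
      blocks[[i]] <- sim$blocks
      truth_records[[length(truth_records) + 1]] <-
        tibble(element_id = ids[i], species = sp, dropout = drop_here,
               true_coverage = sim$truth$true_coverage,
               true_identity = sim$truth$true_identity)
      if (!drop_here) {
        gap <- if (is_linked[i]) linked_distance else unlinked_distance
        qend <- sim$blocks$query_end[1]
        genes[[i]] <- tibble(chrom = "syn1", start = qend + gap,
                             end = qend + gap + 1000,
                             name = sprintf("OR_%s_%02d", sp, i))
      }
    }
    alignments[[sp]] <- dplyr::bind_rows(blocks)
    or_genes[[sp]] <- dplyr::bind_rows(genes)
  }
  truth_records <- dplyr::bind_rows(truth_records)
  truth <- tibble(element_id = ids,
                  syntenic_all = is_syntenic,
                  linked_all = is_linked,
                  retained_synteny = is_syntenic,
                  retained_final = is_syntenic & is_linked)
  out <- list(elements = elements, alignments = alignments,
              or_genes = or_genes, truth = truth,
              truth_records = truth_records, species = species)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(elements = file.path(dir, "elements.bed"))
    write_bed(elements, files$elements)
    for (sp in species) {
      files[[paste0("axt_", sp)]] <- file.path(dir, paste0("ref.", sp, ".axt"))
      write_axt(alignments[[sp]], files[[paste0("axt_", sp)]])
      files[[paste0("or_", sp)]] <- file.path(dir, paste0(sp, ".or_genes.bed"))
      write_bed(or_genes[[sp]], files[[paste0("or_", sp)]])
    }
    files$truth <- file.path(dir, "truth_elements.tsv")
    readr::write_tsv(truth, files$truth)
    files$truth_records <- file.path(dir, "truth_records.tsv")
    readr::write_tsv(truth_records, files$truth_records)
    out$files <- files
  }
  out
}

realize_iupac <- function(pattern) {
  paste(vapply(str_chars(toupper(pattern)), function(ch) {
    cls <- IUPAC_CLASSES[[ch]]
    if (is.null(cls)) abort(sprintf("invalid IUPAC character '%s'", ch))
    if (length(cls) == 1) cls else sample(cls, 1)
  }, character(1)), collapse = "")
}

#' Embed motif instances in a random background sequence
#'
#' Places one concrete realization of each (degenerate) motif at the stated
#' position and strand in an i.i.d. background of the stated GC content.
#' Spurious background occurrences of the motif set are removed by targeted
#' resampling so that, outside the placed intervals, the sequence is free of
#' hits — giving an exact ground truth for scanner tests. (Hits that overlap
#' a placed interval, such as a homeodomain core inside an extended
#' homeodomain placement, are genuine and retained.)
#'
#' @param background_length Sequence length in bp.
#' @param gc_content Background GC fraction (default 0.5).
#' @param placements Tibble with `motif_name`, `position` (0-based), `strand`.
#'   Placements must not overlap.
#' @param seed Integer seed.
#' @param motifs Motif definitions (default [default_motifs()]).
#' @param max_iter Maximum spurious-hit cleanup sweeps.
#' @return List with `sequence` and `placements` (truth tibble including the
#'   realized forward-strand `matched_sequence`).
#' @export
embed_motifs <- function(background_length, gc_content = 0.5,
                         placements = tibble(motif_name = character(),
                                             position = numeric(),
                                             strand = character()),
                         seed = 1, motifs = default_motifs(), max_iter = 200) {
  pat <- setNames(motifs$pattern, motifs$name)
  placements$width <- nchar(pat[placements$motif_name])
  if (nrow(placements) > 0) {
    if (!all(placements$motif_name %in% names(pat))) {
      abort("placement names a motif absent from the motif set")
    }
    placements <- placements[order(placements$position), ]
    if (any(placements$position < 0 |
              placements$position + placements$width > background_length)) {
      abort("placement out of sequence range")
    }
    if (nrow(placements) > 1 &&
          any(placements$position[-1] <
                (placements$position + placements$width)[-nrow(placements)])) {
      abort("overlapping placements")
    }
  }
  withr::with_seed(seed, {
    chars <- str_chars(random_dna(background_length, gc_content))
    matched <- character(nrow(placements))
    for (i in seq_len(nrow(placements))) {
      real <- realize_iupac(pat[[placements$motif_name[i]]])
      if (placements$strand[i] == "-") real <- revcomp(real)
      idx <- placements$position[i] + seq_len(placements$width[i])
      chars[idx] <- str_chars(real)
      matched[i] <- real
    }
    seqs <- paste(chars, collapse = "")
    in_placement <- rep(FALSE, background_length)
    for (i in seq_len(nrow(placements))) {
      in_placement[placements$position[i] + seq_len(placements$width[i])] <- TRUE
    }
    for (iter in seq_len(max_iter)) {
      hits <- iupac_scan(seqs, motifs)
      if (nrow(hits) == 0) break
      w <- nchar(hits$matched_sequence)
      spurious <- vapply(seq_len(nrow(hits)), function(k) {
        !any(in_placement[hits$position[k] + seq_len(w[k])])
      }, logical(1))
      if (!any(spurious)) break
      for (k in which(spurious)) {
        cols <- hits$position[k] + seq_len(w[k])
        j <- sample(cols, 1)
        chars <- str_chars(seqs)
        chars[j] <- sample(setdiff(c("A", "C", "G", "T"), toupper(chars[j])), 1)
        seqs <- paste(chars, collapse = "")
      }
    }
    placements$matched_sequence <- matched
    list(sequence = seqs, placements = placements[, c("motif_name", "position",
                                                      "strand", "width",
                                                      "matched_sequence")])
  })
}

#' Simulate an element-deletion expression experiment over a gene cluster
#'
#' Emulates a two-genotype expression experiment on a clustered gene family
#' spanning several megabases in which deleting a focal element knocks down
#' linked genes with a magnitude that decays exponentially with genomic
#' distance: the mutant-group log2 intensity of a gene at distance `d` is
#' reduced by `max_knockdown_log2 * exp(-d / decay_length)`. Gaussian noise
#' on the log2 scale is added independently per measurement. The defaults
#' describe a ~3-Mb cluster of 200 genes measured in 6 mutant and 6
#' wild-type replicates, with the focal element near one end of the cluster.
#'
#' @param n_genes Number of genes (default 200, > 2 required).
#' @param cluster_span Cluster extent in bp (default 3e6).
#' @param cluster_start Genomic start of the cluster (default 102e6, chrom
#'   `chr7`).
#' @param element_offset Element midpoint offset from the cluster start
#'   (default 1e5 bp).
#' @param max_knockdown_log2 Maximal knockdown in log2 units (default 2).
#' @param decay_length Exponential decay length in bp (default 1.5e6).
#' @param n_replicates_per_group Replicates per genotype (default 6).
#' @param noise_sd_log2 Measurement noise s.d. (default 0.5).
#' @param baseline_log2_mean,baseline_log2_sd Per-gene baseline distribution.
#' @param seed Integer seed.
#' @param dir Optional directory; writes `expression.tsv`, `genes.bed`,
#'   `element.bed`, `truth.tsv`.
#' @return List with `intensities` (log2 matrix), `groups`, `genes`,
#'   `element`, `truth` (per-gene `distance_bp` and `true_log2fc`) and
#'   `expected_r`, the Pearson correlation of the realized true effects with
#'   distance (the value the analysis recovers exactly at zero noise).
#' @export
simulate_cluster_expression <- function(n_genes = 200, cluster_span = 3e6,
                                        cluster_start = 102e6,
                                        element_offset = 1e5,
                                        max_knockdown_log2 = 2,
                                        decay_length = 1.5e6,
                                        n_replicates_per_group = 6,
                                        noise_sd_log2 = 0.3,
                                        baseline_log2_mean = 8,
                                        baseline_log2_sd = 1.5,
                                        seed = 1, dir = NULL) {
  stopifnot(n_genes > 2, decay_length > 0, n_replicates_per_group >= 2)
  withr::with_seed(seed, {
    gene_id <- sprintf("gene_%03d", seq_len(n_genes))
    offs <- sort(runif(n_genes, 0, cluster_span - 1000))
    genes <- tibble(gene_id = gene_id, chrom = "chr7",
                    start = cluster_start + offs,
                    end = cluster_start + offs + 1000,
                    gene_class = "classI")
    el_mid <- cluster_start + element_offset
    element <- genomic_interval("chr7", el_mid - 1000, el_mid + 1000,
                                name = "focal_element")
    distance <- abs((genes$start + genes$end) / 2 - el_mid)
    true_log2fc <- -max_knockdown_log2 * exp(-distance / decay_length)
    n <- n_replicates_per_group
    baseline <- rnorm(n_genes, baseline_log2_mean, baseline_log2_sd)
    wt <- baseline + matrix(rnorm(n_genes * n, 0, noise_sd_log2), n_genes, n)
    mut <- baseline + true_log2fc +
      matrix(rnorm(n_genes * n, 0, noise_sd_log2), n_genes, n)
    intensities <- cbind(wt, mut)
    rownames(intensities) <- gene_id
    colnames(intensities) <- c(sprintf("wt_%d", seq_len(n)),
                               sprintf("mut_%d", seq_len(n)))
    groups <- rep(c("wildtype", "mutant"), each = n)
    truth <- tibble(gene_id = gene_id, distance_bp = distance,
                    true_log2fc = true_log2fc)
    expected_r <- if (sd(true_log2fc) == 0 || sd(distance) == 0) NA_real_ else
      cor(true_log2fc, distance)
    out <- list(intensities = intensities, groups = groups, genes = genes,
                element = element, truth = truth, expected_r = expected_r)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      out$files <- list(expression = file.path(dir, "expression.tsv"),
                        genes = file.path(dir, "genes.bed"),
                        element = file.path(dir, "element.bed"),
                        truth = file.path(dir, "truth.tsv"))
      write_expression_tsv(intensities, out$files$expression)
      write_bed(dplyr::rename(genes, name = "gene_id"), out$files$genes)
      write_bed(element, out$files$element)
      readr::write_tsv(truth, out$files$truth)
    }
    out
  })
}

#' Simulate per-genotype cell-count tables
#'
#' Draws per-group values from normal distributions with the stated means
#' and standard deviations — the generative model behind
#' `mean +/- s.e.m.` cell-count summaries.
#'
#' @param group_means,group_sds,ns Equal-length numeric vectors.
#' @param group_names Optional group labels.
#' @param seed Integer seed.
#' @return Tibble with `group` and `value`.
#' @export
simulate_cell_counts <- function(group_means, group_sds, ns,
                                 group_names = NULL, seed = 1) {
  k <- length(group_means)
  stopifnot(length(group_sds) == k, length(ns) == k, all(ns >= 1),
            all(group_sds >= 0))
  if (is.null(group_names)) group_names <- sprintf("group_%d", seq_len(k))
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(k), function(i) {
      tibble(group = group_names[i],
             value = rnorm(ns[i], group_means[i], group_sds[i]))
    })
  })
}
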