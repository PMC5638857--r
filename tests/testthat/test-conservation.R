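test_that("element alignment extraction accounts for gaps, coverage and overlap resolution", {
  # 10-bp element; 2 reference bases sit opposite query gaps
  blk <- make_block("ACGTACGTAC", "ACG--CTAAC")
  el <- genomic_interval("chr1", 0, 10)
  pairs <- extract_element_alignment(el, blk)
  expect_equal(nrow(pairs), 10)
  expect_equal(sum(pairs$aligned), 8)
  expect_equal(sum(pairs$query_char == "-", na.rm = TRUE), 2)

  ci <- coverage_identity(pairs, 10)
  expect_equal(ci$A, 8)
  expect_equal(ci$coverage, 0.8)
  expect_equal(ci$identity, 0.75)  # 6 of the 8 nucleotide pairs match

  # element fully inside one gapless block: every base paired
  s <- random_seq(50)
  full <- extract_element_alignment(genomic_interval("chr1", 10, 40),
                                    make_block(s, s))
  expect_true(all(full$aligned))

  # element overlapping no block
  none <- extract_element_alignment(genomic_interval("chr9", 0, 10), blk)
  expect_equal(sum(none$aligned), 0)
  expect_equal(coverage_identity(none, 10)$coverage, 0)
  expect_true(is.na(coverage_identity(none, 10)$identity))

  # overlapping blocks: first in file order wins
  b1 <- make_block("AAAA", "AAAA")
  b2 <- make_block("AAAA", "CCCC")
  both <- dplyr::bind_rows(b1, b2)
  expect_message(
    p2 <- extract_element_alignment(genomic_interval("chr1", 0, 4), both),
    "first block")
  expect_equal(coverage_identity(p2, 4)$identity, 1)
})

test_that("conservation index follows the coverage x identity arithmetic", {
  expect_equal(conservation_index(1, 1), 100)
  expect_equal(conservation_index(0.8, 0.9), 72)
  expect_equal(conservation_index(0, 0.5), 0)
  expect_equal(conservation_index(0.5, NA), 0)  # undefined identity -> 0
  # index bounded by each percentage
  set.seed(3)
  cv <- runif(100); id <- runif(100)
  idx <- conservation_index(cv, id)
  expect_true(all(idx <= pmin(100 * cv, 100 * id) + 1e-12))
  expect_true(all(idx >= 0 & idx <= 100))
})

test_that("coverage and identity equal a per-column brute-force recount on random fixtures", {
  for (s in 1:10) {
    sim <- simulate_pairwise_alignment(400, runif(1, 0, 0.4),
                                       indel_rate = runif(1, 0, 0.1), seed = s)
    pairs <- extract_element_alignment(genomic_interval("chrR", 0, 400), sim$blocks)
    ci <- coverage_identity(pairs, 400)
    m <- oracle_match_vector(sim$blocks, 0, 400)
    # oracle recount of A: columns where ref base faces a query nucleotide
    rch <- strsplit(sim$blocks$ref_row, "")[[1]]
    qch <- strsplit(sim$blocks$query_row, "")[[1]]
    A_oracle <- sum(rch != "-" & qch != "-")
    expect_equal(ci$A, A_oracle)
    expect_equal(ci$identity, sum(m) / A_oracle)
    # and both equal the generator's own truth
    expect_equal(ci$coverage, sim$truth$true_coverage)
    expect_equal(ci$identity, sim$truth$true_identity)
  }
})

test_that("adding a matching aligned pair never decreases coverage or index", {
  el <- genomic_interval("chr1", 0, 8)
  blk_small <- make_block("ACGTAC", "ACGAAC")
  p_small <- extract_element_alignment(el, blk_small)
  ci_small <- coverage_identity(p_small, 8)
  blk_big <- make_block("ACGTACG", "ACGAACG")    # one extra matching pair
  ci_big <- coverage_identity(extract_element_alignment(el, blk_big), 8)
  expect_gte(ci_big$coverage, ci_small$coverage)
  expect_gte(conservation_index(ci_big$coverage, ci_big$identity),
             conservation_index(ci_small$coverage, ci_small$identity))
})

test_that("the all-species filter eliminates elements missing from any alignment", {
  rec <- tidyr::expand_grid(element_id = c("e1", "e2"),
                            species = paste0("sp", 1:7))
  rec$syntenic_found <- TRUE
  rec$syntenic_found[rec$element_id == "e2" & rec$species == "sp4"] <- FALSE
  kept <- filter_all_species(rec, paste0("sp", 1:7))
  expect_equal(kept, "e1")

  # missing records are treated as not found
  rec2 <- rec[!(rec$element_id == "e1" & rec$species == "sp7"), ]
  rec2$syntenic_found[rec2$element_id == "e2"] <- TRUE
  expect_message(kept2 <- filter_all_species(rec2, paste0("sp", 1:7)), "missing")
  expect_equal(kept2, "e2")
})

test_that("OR linkage uses inclusive 1-Mb edge-to-edge distance on the same sequence", {
  loc <- tibble::tibble(element_id = "e", species = "sp",
                        query_chrom = "scaf1", query_start = 1000, query_end = 3000)
  genes <- function(start, end, chrom = "scaf1") {
    list(sp = tibble::tibble(chrom = chrom, start = start, end = end, name = "or1"))
  }
  expect_true(link_nearest_or(loc, genes(1500, 2500))$linked)        # overlap
  expect_equal(link_nearest_or(loc, genes(1500, 2500))$distance, 0)
  expect_true(link_nearest_or(loc, genes(3000 + 1e6, 3000 + 1e6 + 100))$linked)
  expect_false(link_nearest_or(loc, genes(3000 + 1e6 + 1, 3000 + 1e6 + 101))$linked)
  expect_false(link_nearest_or(loc, genes(3500, 4000, chrom = "scaf2"))$linked)
  empty <- link_nearest_or(loc, list(sp = tibble::tibble(chrom = character(),
                                                         start = numeric(),
                                                         end = numeric(),
                                                         name = character())))
  expect_false(empty$linked)
  expect_true(is.na(empty$nearest_or))
})

test_that("ranking is deterministic and puts the uniformly best element first", {
  panel <- simulate_enhancer_panel(n_elements = 8, n_syntenic_all = 8,
                                   n_or_linked = 8, seed = 11)
  rec <- score_conservation(panel$elements, panel$alignments)
  rk <- rank_elements(rec)
  # element 1 is generated with the lowest substitution rate in every species
  by_el <- split(rec$conservation_index, rec$element_id)
  expect_true(all(vapply(by_el[names(by_el) != "elem_01"], max, numeric(1)) <
                    min(by_el$elem_01)))
  expect_equal(rk$element_id[1], "elem_01")
  expect_equal(rk$rank_min[rk$element_id == "elem_01"], 1)

  # permuting input row order leaves the ranking unchanged
  set.seed(1)
  rk2 <- rank_elements(rec[sample.int(nrow(rec)), ])
  expect_equal(rk, rk2)
})

test_that("the designed synteny and linkage funnel is reproduced end to end", {
  panel <- simulate_enhancer_panel(seed = 17)
  rec <- score_conservation(panel$elements, panel$alignments)
  kept <- filter_all_species(rec, panel$species)
  expect_equal(length(kept), 21)
  expect_equal(sort(kept), sort(panel$truth$element_id[panel$truth$retained_synteny]))

  linkage <- link_nearest_or(rec[rec$element_id %in% kept & rec$syntenic_found, ],
                             panel$or_genes)
  linked_all <- tapply(linkage$linked, linkage$element_id, all)
  expect_equal(sum(linked_all), 15)
  expect_equal(sort(names(linked_all)[linked_all]),
               sort(panel$truth$element_id[panel$truth$retained_final]))
})
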