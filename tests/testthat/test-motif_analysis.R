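test_that("degenerate scanning matches the worked examples and handles N conservatively", {
  expect_equal(nrow(dplyr::filter(iupac_scan("TAATGA"), .data$strand == "+",
                                  .data$position == 0,
                                  .data$motif_name == "homeodomain")), 1)

  # reverse-complement symmetry of the class I-specific site
  h <- iupac_scan("GAAAAGTTT")
  h <- h[h$motif_name == "class1_specific", ]
  expect_equal(nrow(h), 1)
  expect_equal(h$strand, "-")
  expect_equal(h$position, 0)

  # the extended homeodomain site contains exactly one forward homeodomain core
  hd <- iupac_scan("AACTTTTTAATGA")
  hd <- hd[hd$motif_name == "homeodomain", ]
  expect_equal(nrow(hd), 1)
  expect_equal(hd$strand, "+")
  expect_equal(hd$position, 7)

  # N in the sequence matches nothing
  expect_equal(nrow(iupac_scan("TAATGN", both_strands = FALSE)), 0)
  # lower case matches
  expect_equal(nrow(dplyr::filter(iupac_scan("taatga"),
                                  .data$motif_name == "homeodomain",
                                  .data$strand == "+")), 1)
  # invalid pattern character errors at load
  expect_error(iupac_scan("ACGT", tibble::tibble(name = "bad", pattern = "AXG")),
               "invalid IUPAC")
})

test_that("the default motif set is the four canonical enhancer motifs", {
  m <- default_motifs()
  expect_setequal(m$pattern, c("TAATKR", "YYYCARRRR", "AAACTTTTC",
                               "AACTTTTTAATGA"))
})

test_that("scanning equals the brute-force both-strand oracle on random sequences", {
  motifs <- default_motifs()
  set.seed(99)
  for (i in 1:60) {
    s <- random_seq(sample(20:80, 1))
    got <- iupac_scan(s, motifs)
    want <- oracle_iupac_scan(s, motifs)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      expect_equal(got$position, want$position)
      expect_equal(got$strand, want$strand)
      expect_equal(got$motif_name, want$motif_name)
    }
  }
})

test_that("strand symmetry: scanning the reverse complement mirrors hits exactly", {
  motifs <- default_motifs()
  set.seed(123)
  for (i in 1:40) {
    s <- random_seq(60)
    a <- iupac_scan(s, motifs)
    b <- iupac_scan(revcomp(s), motifs)
    flip <- function(h, L) {
      h$position <- L - h$position - nchar(h$matched_sequence)
      h$strand <- as.character(ifelse(h$strand == "+", "-", "+"))
      h$position <- as.numeric(h$position)
      h[order(h$position, h$strand, h$motif_name), c("motif_name", "position", "strand")]
    }
    expect_equal(flip(b, 60),
                 a[order(a$position, a$strand, a$motif_name),
                   c("motif_name", "position", "strand")],
                 ignore_attr = TRUE)
  }
})

test_that("core-window detection recovers a designed motif cluster", {
  pl <- tibble::tibble(
    motif_name = c("class1_specific", "homeodomain", "extended_homeodomain",
                   "homeodomain", "oe_like", "homeodomain"),
    position = c(1010, 1060, 1110, 1170, 1250, 1330),
    strand = c("+", "+", "+", "-", "+", "-"))
  fix <- embed_motifs(2000, placements = pl, seed = 31)
  hits <- iupac_scan(fix$sequence)
  core <- find_core_window(hits, 2000, window = 430)
  expect_false(is.null(core))
  # every placed motif lies inside the detected window
  expect_true(all(pl$position >= core$interval$start &
                    pl$position + nchar(fix$placements$matched_sequence) <=
                      core$interval$end))
  expect_gte(length(unique(core$hits$motif_name)), 2)

  # all hits inside one short span: the window contains them all
  pl2 <- tibble::tibble(motif_name = c("homeodomain", "oe_like"),
                        position = c(100, 200), strand = c("+", "+"))
  fix2 <- embed_motifs(1000, placements = pl2, seed = 32)
  hits2 <- iupac_scan(fix2$sequence)
  core2 <- find_core_window(hits2, 1000, window = 430)
  expect_equal(nrow(core2$hits), nrow(hits2))

  # zero hits -> nothing to report
  expect_null(find_core_window(hits2[0, ], 1000, window = 430))
  # a single motif class cannot satisfy the two-class requirement
  only_hd <- hits2[hits2$motif_name == "homeodomain", ]
  expect_null(find_core_window(only_hd, 1000, window = 430, min_motif_classes = 2))
})

test_that("profile construction follows frequencies and recovers a consensus", {
  ident <- setNames(rep("ACGTTGCA", 4), paste0("s", 1:4))
  m <- build_profile(ident)
  cons_idx <- cbind(seq_len(m$length),
                    match(strsplit(m$consensus, "")[[1]], c("A", "C", "G", "T")))
  expect_true(all(m$log_odds[cons_idx] > 0))
  off <- m$log_odds; off[cons_idx] <- NA
  expect_true(all(off < 0, na.rm = TRUE))
  expect_equal(m$consensus, "ACGTTGCA")

  # frequency monotonicity: an A/A column scores A higher than an A/T column
  two <- build_profile(c(x = "AA", y = "AT"))
  expect_gt(two$log_odds[1, "A"], two$log_odds[2, "A"])

  # probability rows sum to 1
  expect_equal(unname(rowSums(two$probs)), rep(1, 2))

  # majority-gap columns are dropped
  gappy <- build_profile(c(a = "A-CG", b = "A-CG", c = "ATCG"))
  expect_equal(gappy$length, 3)

  expect_error(build_profile(c(a = "ACGT")), "at least two")
  expect_error(build_profile(c(a = "ACGT", b = "ACG")), "unequal")

  # variants simulated from a common ancestor recover the generating consensus
  withr::with_seed(77, {
    anc <- random_seq(100)
    vars <- vapply(1:7, function(i) {
      ch <- strsplit(anc, "")[[1]]
      mut <- runif(100) < 0.05
      ch[mut] <- vapply(ch[mut], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
      paste(ch, collapse = "")
    }, character(1))
    prof <- build_profile(setNames(vars, paste0("sp", 1:7)))
    expect_equal(prof$consensus, anc)
  })
})

test_that("profile search finds embedded instances with deterministic tie-breaks", {
  withr::with_seed(55, {
    anc <- random_seq(60)
    vars <- setNames(rep(anc, 3), paste0("s", 1:3))
    model <- build_profile(vars)
    for (i in 1:20) {
      bg <- random_seq(400)
      pos <- sample(0:(400 - 60), 1)
      target <- paste0(substr(bg, 1, pos), anc, substr(bg, pos + 61, 400))
      hit <- profile_top_hit(model, target)
      expect_equal(hit$position, pos)
      expect_equal(hit$strand, "+")
      # reverse complement: minus strand at the mirrored position
      rhit <- profile_top_hit(model, revcomp(target))
      expect_equal(rhit$strand, "-")
      expect_equal(rhit$position, nchar(target) - pos - 60)
      expect_equal(rhit$score, hit$score)
    }
    # translation invariance: prepending background shifts the position
    bg2 <- random_seq(50)
    t1 <- paste0(random_seq(10), anc, random_seq(10))
    t2 <- paste0(bg2, t1)
    h1 <- profile_top_hit(model, t1)
    h2 <- profile_top_hit(model, t2)
    expect_equal(h2$position, h1$position + 50)
    expect_equal(h2$score, h1$score)
  })

  # all-zero model: score 0 everywhere, leftmost + returned
  flat <- structure(list(log_odds = matrix(0, 3, 4,
                                           dimnames = list(NULL, c("A", "C", "G", "T"))),
                         length = 3), class = "profile_model")
  h <- profile_top_hit(flat, "ACGTACGT")
  expect_equal(h$position, 0)
  expect_equal(h$strand, "+")
  expect_equal(h$score, 0)
})
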