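test_that("CDS extraction respects strand and phase", {
  genome <- c(chr = "ATGNNNGAATAGCCC")
  m_plus <- gene_model("t", "g", "chr", "+",
                       exons = rbind(c(1L, 3L), c(7L, 12L)),
                       cds = rbind(c(1L, 3L, 0L), c(7L, 9L, 0L)))
  expect_equal(extract_cds(m_plus, genome), "ATGGAA")

  ## minus strand: reverse complement, right-to-left
  m_minus <- gene_model("t", "g", "chr", "-",
                        exons = rbind(c(1L, 3L), c(7L, 12L)),
                        cds = rbind(c(1L, 3L, 0L), c(7L, 9L, 0L)))
  expect_equal(extract_cds(m_minus, genome), rc("ATGGAA"))

  ## phase on the first transcript interval trims leading bases
  m_phase <- gene_model("t", "g", "chr", "+",
                        exons = rbind(c(1L, 7L)),
                        cds = rbind(c(1L, 7L, 1L)))
  ## manual phase arithmetic on the 7-bp toy CDS: drop 1 base
  expect_equal(extract_cds(m_phase, genome), substr("ATGNNNG", 2, 7))

  m_oob <- gene_model("t", "g", "chr", "+", exons = rbind(c(10L, 99L)),
                      cds = rbind(c(10L, 99L, 0L)))
  expect_error(extract_cds(m_oob, genome), "out of bounds")
})

test_that("translation flags structural problems without raising", {
  t1 <- translate_cds("ATGGAATAA")
  expect_equal(t1$protein, "ME")
  expect_equal(t1$flags, character(0))

  t2 <- translate_cds("ATGTAAGAA")
  expect_true("internal_stop" %in% t2$flags)

  t3 <- translate_cds("ATGGAAGAAG")  # 10 bp
  expect_true("incomplete_codon" %in% t3$flags)
  expect_equal(nchar(t3$protein), 3L)

  t4 <- translate_cds("GTGGAATAA")
  expect_true("no_start" %in% t4$flags)
})

test_that("global alignment matches the independent DP oracle", {
  th <- qc_thresholds()
  p <- random_protein(30)
  self <- global_align(p, p, th)
  expect_equal(self$identity, 100)
  expect_equal(self$similarity, 100)
  expect_equal(self$gap_positions, 0L)

  ## K/R scores +2 in BLOSUM62: similar but not identical
  kr <- global_align("MKV", "MRV", th)
  expect_equal(kr$identity, 200 / 3, tolerance = 1e-6)
  expect_equal(kr$similarity, 100)
  expect_equal(kr$gap_positions, 0L)
  expect_equal(kr$score, nw_score_oracle("MKV", "MRV", blosum62_test))

  set.seed(20)
  for (i in 1:60) {
    a <- random_protein(sample(1:12, 1))
    b <- random_protein(sample(1:12, 1))
    expect_equal(global_align(a, b, th)$score,
                 nw_score_oracle(a, b, blosum62_test),
                 tolerance = 1e-9)
  }

  expect_error(global_align("MK*", "MKV", th), "non-amino-acid")
})

test_that("alignment statistics satisfy their structural invariants", {
  set.seed(21)
  for (i in 1:25) {
    a <- random_protein(sample(5:40, 1))
    b <- random_protein(sample(5:40, 1))
    al <- global_align(a, b)
    expect_gte(al$similarity, al$identity)
    expect_lte(al$similarity, 100)
    expect_gte(al$gap_positions, abs(nchar(a) - nchar(b)))
    rows <- strsplit(al$alignment, "")
    expect_equal(length(rows[[1]]), length(rows[[2]]))
    ## each row spells its full input sequence once the gaps are removed
    expect_equal(paste(rows[[1]][rows[[1]] != "-"], collapse = ""), a)
    expect_equal(paste(rows[[2]][rows[[2]] != "-"], collapse = ""), b)
  }
})

test_that("the acceptance rule applies strict inequalities and is monotone", {
  cmp <- function(dl, sim) list(len_test = 100 + dl, len_ref = 100,
                                similarity = sim, flags = character(0))
  expect_equal(evaluate_model(cmp(4, 93)), "accept")
  expect_equal(evaluate_model(cmp(5, 99)), "flag_for_review")
  expect_equal(evaluate_model(cmp(0, 92)), "flag_for_review")

  ## fast-evolving class relaxes cutoffs
  expect_equal(evaluate_model(cmp(10, 85), "fast_evolving"), "accept")
  expect_equal(evaluate_model(cmp(10, 85), "default"), "flag_for_review")

  ## structural flags always force review
  c_flag <- cmp(0, 99); c_flag$flags <- "internal_stop"
  expect_equal(evaluate_model(c_flag), "flag_for_review")

  ## monotone: raising similarity or lowering length difference never
  ## turns an accept into a flag
  set.seed(22)
  for (i in 1:50) {
    dl <- sample(0:10, 1); sim <- runif(1, 85, 100)
    d1 <- evaluate_model(cmp(dl, sim))
    if (d1 == "accept") {
      expect_equal(evaluate_model(cmp(dl, min(100, sim + runif(1, 0, 5)))),
                   "accept")
      expect_equal(evaluate_model(cmp(max(0, dl - sample(0:3, 1)), sim)),
                   "accept")
    }
  }
})

test_that("non-coding terminal exons merge across short gaps only", {
  mk <- function(gap, term_cds = FALSE) {
    ex <- rbind(c(100L, 500L), c(600L, 700L), c(700L + gap + 1L, 900L + gap))
    cds <- if (term_cds)
      rbind(c(150L, 500L, 0L), c(700L + gap + 1L, 800L + gap, 0L))
    else rbind(c(150L, 500L, 0L))
    gene_model("t", "g", "chr1", "+", ex, cds)
  }
  merged <- merge_terminal_exons(mk(900L))
  expect_equal(nrow(merged$exons), 2L)
  expect_equal(unname(merged$exons[2L, ]), c(600L, 1800L))
  expect_equal(merged$cds, mk(900L)$cds)  # CDS untouched

  expect_equal(merge_terminal_exons(mk(1100L))$exons, mk(1100L)$exons)

  ## coding guard: terminal exon carries CDS -> unchanged
  expect_equal(merge_terminal_exons(mk(900L, term_cds = TRUE))$exons,
               mk(900L, term_cds = TRUE)$exons)

  ## minus strand: terminal exon is the leftmost
  exm <- rbind(c(100L, 200L), c(1000L, 1100L), c(1200L, 1500L))
  mm <- gene_model("t", "g", "chr1", "-", exm,
                   rbind(c(1250L, 1450L, 0L)))
  out <- merge_terminal_exons(mm)
  expect_equal(nrow(out$exons), 2L)
  expect_equal(unname(out$exons[1L, ]), c(100L, 1100L))
})

test_that("terminal-UTR projection extends only through gap-free sequence", {
  genome <- c(chr1 = paste0(random_dna(960), strrep("N", 20),
                            random_dna(20)))
  m <- gene_model("t", "g", "chr1", "+", rbind(c(1L, 300L)),
                  rbind(c(1L, 240L, 0L)))
  ext <- extend_terminal_utr(m, genome, ref_utr_len = 200L)
  expect_equal(unname(ext$exons[1L, 2L]), 440L)
  ## extension blocked by an N run
  ext2 <- extend_terminal_utr(m, genome, ref_utr_len = 800L)
  expect_equal(ext2$exons, m$exons)
})

test_that("GTF validation reports issues, removes duplicates, idempotent", {
  raw <- list(
    list(transcript_id = "tBad", gene_id = "g1", gene_name = "g1",
         gene_description = "", chrom = "c", strand = "+",
         exons = rbind(c(1L, 40L), c(70L, 100L)),
         cds = rbind(c(50L, 60L, 0L))),
    list(transcript_id = "tB", gene_id = "g2", gene_name = "g2",
         gene_description = "", chrom = "c", strand = "+",
         exons = rbind(c(1L, 100L)), cds = rbind(c(10L, 90L, 0L))),
    list(transcript_id = "tA", gene_id = "g2", gene_name = "g2",
         gene_description = "", chrom = "c", strand = "+",
         exons = rbind(c(1L, 100L)), cds = rbind(c(10L, 90L, 0L))))
  v <- validate_gtf(raw)
  expect_true("cds_without_exon" %in% v$issues$issue)
  expect_true("duplicate_transcript" %in% v$issues$issue)
  expect_equal(names(v$models), "tA")  # smallest id kept

  ## idempotence on the clean output
  v2 <- validate_gtf(v$models)
  expect_equal(nrow(v2$issues), 0L)
  expect_equal(names(v2$models), names(v$models))

  ## clean input: identity
  clean <- list(tX = gene_model("tX", "g", "c", "+",
                                rbind(c(1L, 90L)), rbind(c(1L, 90L, 0L))))
  v3 <- validate_gtf(clean)
  expect_equal(nrow(v3$issues), 0L)
  expect_equal(v3$models$tX$exons, clean$tX$exons)
})

test_that("comparison summaries are plain means", {
  cm <- data.frame(identity = c(90, 100), similarity = c(95, 99),
                   gap_positions = c(0L, 4L))
  s <- summarize_comparisons(cm)
  expect_equal(s$mean_identity, 95)
  expect_equal(s$n, 2L)
  s1 <- summarize_comparisons(cm[1, ])
  expect_equal(s1$mean_similarity, 95)
  expect_error(summarize_comparisons(cm[0, ]), "no comparisons")

  ## independent recomputation over simulated comparisons
  set.seed(23)
  sim <- data.frame(identity = runif(50, 80, 100),
                    similarity = runif(50, 85, 100),
                    gap_positions = rpois(50, 2))
  s50 <- summarize_comparisons(sim)
  expect_equal(s50$mean_identity, sum(sim$identity) / 50)
  expect_equal(s50$mean_gaps, sum(sim$gap_positions) / 50)
})

test_that("true simulated models pass QC; frameshifts never do", {
  w <- small_world()
  qc <- qc_gene_models(w$truth$models, w$scaffolds, w$reference$proteome,
                       w$reference$pairing)
  expect_equal(mean(qc$comparisons$decision == "accept"), 1)
  expect_equal(nrow(qc$issues), 0L)

  ## plant a 1-bp frameshift in each model's first CDS interval
  shifted <- lapply(w$truth$models[1:8], function(m) {
    m$cds[1L, "end"] <- m$cds[1L, "end"] - 1L
    m
  })
  cmp <- compare_proteins(shifted, w$scaffolds, w$reference$proteome,
                          w$reference$pairing)
  expect_true(all(cmp$decision != "accept"))
  expect_true(all(grepl("internal_stop|incomplete_codon", cmp$flags) |
                  abs(cmp$len_test - cmp$len_ref) >= 5))
})
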