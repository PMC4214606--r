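test_that("contiguity violations are classified correctly", {
  ## clean plus-strand gene
  ok <- make_evidence("gA", 1:3, "s1", c(100L, 500L, 900L),
                      c(150L, 550L, 950L), "+")
  expect_equal(nrow(detect_violations(ok)), 0L)

  ## clean minus-strand gene: decreasing t_start in transcript order
  okm <- make_evidence("gB", 1:3, "s1", c(950L, 550L, 150L),
                       c(900L, 500L, 100L), "-")
  expect_equal(nrow(detect_violations(okm)), 0L)

  ## order violation
  oo <- make_evidence("gC", 1:3, "s1", c(100L, 900L, 500L),
                      c(150L, 950L, 550L), "+")
  v <- detect_violations(oo)
  expect_equal(v$kind, "order_violation")

  ## split gene: exons 1-2 on s1, exon 3 on s2 (the classic pattern of a
  ## gene whose terminal exon lands on a mis-assigned scaffold)
  sp <- make_evidence("gD", 1:3, c("s1", "s1", "s2"),
                      c(100L, 500L, 200L), c(150L, 550L, 250L), "+")
  v <- detect_violations(sp)
  expect_equal(v$kind, "split_gene")
  expect_equal(v$scaffolds, "s1,s2")

  ## orientation violation
  ov <- make_evidence("gE", 1:2, "s1", c(100L, 600L), c(150L, 550L),
                      c("+", "-"))
  expect_true("orientation_violation" %in% detect_violations(ov)$kind)
})

test_that("violation detection is invariant to input row order", {
  ev <- rbind(
    make_evidence("gC", 1:3, "s1", c(100L, 900L, 500L),
                  c(150L, 950L, 550L), "+"),
    make_evidence("gD", 1:3, c("s1", "s1", "s2"),
                  c(100L, 500L, 200L), c(150L, 550L, 250L), "+"))
  v1 <- detect_violations(ev)
  set.seed(1)
  for (i in 1:5) {
    v2 <- detect_violations(ev[sample(nrow(ev)), ])
    expect_equal(v2[order(v2$gene_id), ], v1[order(v1$gene_id), ],
                 ignore_attr = TRUE)
  }
})

test_that("chimera detection clusters genes by chromosome vote", {
  ev2 <- function(g, s, lo) make_evidence(g, 1:2, s, c(lo, lo + 2000L),
                                          c(lo + 100L, lo + 2100L), "+")
  votes <- data.frame(gene_id = paste0("g", 1:6),
                      chrom = c("1", "1", "2", "2", "1", "1"),
                      stringsAsFactors = FALSE)
  ## chr1 genes at 0-10kb, chr2 genes at 20-30kb
  ev <- rbind(ev2("g1", "sX", 1000L), ev2("g2", "sX", 6000L),
              ev2("g3", "sX", 21000L), ev2("g4", "sX", 26000L))
  ch <- detect_chimeras(ev, votes)
  expect_named(ch$clusters, "sX")
  expect_equal(nrow(ch$clusters$sX), 2L)
  expect_equal(ch$clusters$sX$chrom, c("1", "2"))

  ## all genes agree -> not flagged
  ev_ok <- rbind(ev2("g1", "sY", 1000L), ev2("g2", "sY", 6000L))
  expect_equal(length(detect_chimeras(ev_ok, votes)$clusters), 0L)

  ## votes 1,1,2,2,1,1 along the scaffold -> 3 maximal runs (2 breaks);
  ## verified against a direct rle over the sorted gene positions
  ev3 <- rbind(ev2("g1", "sZ", 1000L), ev2("g2", "sZ", 6000L),
               ev2("g3", "sZ", 11000L), ev2("g4", "sZ", 16000L),
               ev2("g5", "sZ", 21000L), ev2("g6", "sZ", 26000L))
  ch3 <- detect_chimeras(ev3, votes)
  expect_equal(nrow(ch3$clusters$sZ), 3L)
  brute <- rle(votes$chrom[match(paste0("g", 1:6), votes$gene_id)])
  expect_equal(ch3$clusters$sZ$chrom, brute$values)

  ## a single interleaved foreign gene is noise, not a break trigger
  votes1 <- data.frame(gene_id = paste0("g", 1:3),
                       chrom = c("1", "2", "1"), stringsAsFactors = FALSE)
  ev1 <- rbind(ev2("g1", "sW", 1000L), ev2("g2", "sW", 6000L),
               ev2("g3", "sW", 11000L))
  ch1 <- detect_chimeras(ev1, votes1)
  expect_equal(length(ch1$clusters), 0L)
  expect_equal(ch1$noise$gene_id, "g2")
})

test_that("breakpoints fall in the longest N-run, else the gap midpoint", {
  clusters <- data.frame(chrom = c("1", "2"),
                         start = c(1L, 20000L), end = c(10000L, 30000L),
                         n_genes = c(3L, 3L), stringsAsFactors = FALSE)
  seq_n <- paste0(strrep("A", 14000), strrep("N", 100), strrep("C", 15900))
  bp <- propose_breakpoints(clusters, seq_n, "s1")
  expect_equal(bp$coordinate, 14050L)
  expect_equal(bp$evidence_left, "1")
  expect_equal(bp$evidence_right, "2")

  seq_plain <- strrep("A", 30000)
  expect_equal(propose_breakpoints(clusters, seq_plain, "s1")$coordinate,
               15000L)

  ## two N-runs (50 bp and 200 bp): break inside the longer one
  seq_two <- paste0(strrep("A", 12000), strrep("N", 50), strrep("A", 2000),
                    strrep("N", 200), strrep("C", 15750))
  bp2 <- propose_breakpoints(clusters, seq_two, "s1")
  expect_gte(bp2$coordinate, 14051L)
  expect_lte(bp2$coordinate, 14250L)

  bad <- clusters; bad$start[2] <- 5000L
  expect_error(propose_breakpoints(bad, seq_plain, "s1"), "overlap")
})

test_that("apply_breaks conserves sequence and names parts left-to-right", {
  s <- c(sc = random_dna(30000))
  bp <- data.frame(scaffold_id = "sc", coordinate = 14050L)
  br <- apply_breaks(s, bp)
  expect_equal(names(br$scaffolds), c("sc.1", "sc.2"))
  expect_equal(nchar(br$scaffolds), c(sc.1 = 14050L, sc.2 = 15950L))
  expect_equal(paste0(br$scaffolds[["sc.1"]], br$scaffolds[["sc.2"]]),
               s[["sc"]])
  expect_equal(br$provenance$parent_start, c(1L, 14051L))

  ## no breakpoints: identity
  br0 <- apply_breaks(s, bp[0, ])
  expect_identical(br0$scaffolds, s)
  expect_equal(nrow(br0$provenance), 0L)

  ## two breaks: three parts, concatenation restores the parent
  bp2 <- data.frame(scaffold_id = "sc", coordinate = c(10000L, 20000L))
  br2 <- apply_breaks(s, bp2)
  expect_equal(length(br2$scaffolds), 3L)
  expect_equal(paste(br2$scaffolds, collapse = ""), s[["sc"]])
  expect_equal(sum(nchar(br2$scaffolds)), nchar(s[["sc"]]))

  expect_error(apply_breaks(s, data.frame(scaffold_id = "sc",
                                          coordinate = 30000L)),
               "out of range")
})

test_that("planted chimeras are found and broken inside their junction gap", {
  w <- small_world()
  cur <- small_curation()
  junc <- w$truth$junctions
  flagged <- names(cur$chimeras$clusters)
  expect_setequal(flagged, unique(junc$scaffold_id))  # all and only
  bp <- cur$breakpoints
  for (i in seq_len(nrow(bp))) {
    j <- junc[junc$scaffold_id == bp$scaffold_id[i], ]
    expect_true(any(j$gap_start <= bp$coordinate[i] &
                    j$gap_end >= bp$coordinate[i]))
  }
  ## conservation across the whole break step
  expect_equal(sum(nchar(cur$scaffolds)), sum(nchar(w$scaffolds)))
})
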