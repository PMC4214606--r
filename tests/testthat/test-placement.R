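test_that("marker placement orders, orients and flags conflicts", {
  set.seed(8)
  m5 <- random_dna(120); m6 <- random_dna(120); m7 <- random_dna(120)
  fwd <- paste0(random_dna(500), m5, random_dna(500), m6,
                random_dna(500), m7, random_dna(500))
  markers <- data.frame(marker_id = c("m5", "m6", "m7"), chrom = "3",
                        order_index = 5:7,
                        sequence = c(m5, m6, m7), stringsAsFactors = FALSE)
  d <- place_by_markers(markers, build_index(c(sF = fwd)))
  expect_equal(d$chrom, "3")
  expect_equal(d$marker_key, 6)   # median order_index
  expect_equal(d$tier, 1L)
  expect_equal(d$orientation, "+")

  ## disagreement on chromosome -> conflict, unplaced
  markers2 <- markers; markers2$chrom <- c("1", "3", "3")
  d2 <- place_by_markers(markers2, build_index(c(sF = fwd)))
  expect_false(d2$placed)
  expect_match(d2$conflicts, "disagree")
})

test_that("marker orientation follows the order/offset correlation", {
  set.seed(9)
  ms <- vapply(1:3, function(i) random_dna(120), character(1))
  body <- paste0(random_dna(300), ms[1], random_dna(300), ms[2],
                 random_dna(300), ms[3], random_dna(300))
  markers <- data.frame(marker_id = paste0("k", 1:3), chrom = "2",
                        order_index = 1:3, sequence = ms,
                        stringsAsFactors = FALSE)
  dF <- place_by_markers(markers, build_index(c(s = body)))
  expect_equal(dF$orientation, "+")
  dR <- place_by_markers(markers, build_index(c(s = rc(body))))
  expect_equal(dR$orientation, "-")
})

test_that("synteny placement reflects minus-orientation blocks", {
  ## two genes, ref positions 1000 < 5000, block maps ref1 -> target 2
  meta <- rbind(
    data.frame(exon_id = "gA.e1", gene_id = "gA", exon_index = 1L,
               ref_chrom = "ref1", ref_start = 950L, ref_end = 1050L,
               ref_strand = "+", stringsAsFactors = FALSE),
    data.frame(exon_id = "gB.e1", gene_id = "gB", exon_index = 1L,
               ref_chrom = "ref1", ref_start = 4950L, ref_end = 5050L,
               ref_strand = "+", stringsAsFactors = FALSE))
  synteny_p <- data.frame(ref_chrom = "ref1", ref_start = 1L,
                          ref_end = 10000L, target_chrom = "2",
                          block_orientation = "+", block_order = 1L,
                          stringsAsFactors = FALSE)
  ev <- rbind(make_evidence("gA", 1L, "s1", 100L, 200L, "+"),
              make_evidence("gB", 1L, "s2", 100L, 200L, "+"))
  ev$ref_start <- c(950L, 4950L); ev$ref_end <- c(1050L, 5050L)
  meta_ev <- meta  # evidence carries the metadata columns already
  ev$ref_chrom <- "ref1"

  dp <- place_by_synteny(c("s1", "s2"), ev, synteny_p)
  expect_equal(dp$chrom, c("2", "2"))
  expect_true(dp$within_key[dp$scaffold_id == "s1"] <
              dp$within_key[dp$scaffold_id == "s2"])
  expect_equal(dp$orientation, c("+", "+"))

  ## minus block: within-block order reversed, orientation flipped
  synteny_m <- synteny_p; synteny_m$block_orientation <- "-"
  dm <- place_by_synteny(c("s1", "s2"), ev, synteny_m)
  expect_true(dm$within_key[dm$scaffold_id == "s1"] >
              dm$within_key[dm$scaffold_id == "s2"])
  expect_equal(dm$orientation, c("-", "-"))

  ## brute-force reflection check: sorting by within_key equals sorting
  ## by reflected reference position
  refpos <- c(s1 = 1000, s2 = 5000)
  expect_equal(dm$scaffold_id[order(dm$within_key)],
               names(sort(-refpos)))
})

test_that("tiling placement votes with segments, including short terminals", {
  set.seed(10)
  ref <- c(ref1 = random_dna(25000))
  synteny <- data.frame(ref_chrom = "ref1", ref_start = 1L,
                        ref_end = 25000L, target_chrom = "1",
                        block_orientation = "+", block_order = 1L,
                        stringsAsFactors = FALSE)
  scafs <- c(u1 = substr(ref[["ref1"]], 8001, 18000),
             u2 = substr(ref[["ref1"]], 20001, 25000),  # terminal 5-kb segment
             u3 = random_dna(4000))                     # no reference origin
  d <- place_by_tiling(scafs, ref, synteny)
  d <- d[order(d$scaffold_id), ]
  expect_equal(d$scaffold_id[d$placed], c("u1", "u2"))
  expect_true(d$within_key[d$scaffold_id == "u1"] <
              d$within_key[d$scaffold_id == "u2"])
  expect_equal(d$orientation[d$placed], c("+", "+"))
  expect_false("u3" %in% d$scaffold_id)  # no hits -> left for the unplaced list

  ## reverse-complemented scaffold -> minus orientation
  d2 <- place_by_tiling(c(u1 = rc(scafs[["u1"]])), ref, synteny)
  expect_equal(d2$orientation, "-")
})

test_that("merge_placements applies overrides and accounts for every scaffold", {
  dec <- rbind(
    placement_row("a", chrom = "1", tier = 2L, orientation = "+",
                  block_order = 1, within_key = 100),
    placement_row("b", chrom = "1", tier = 2L, orientation = "+",
                  block_order = 1, within_key = 200),
    placement_row("c", chrom = "1", tier = 2L, orientation = "+",
                  block_order = 2, within_key = 50),
    placement_row("d"))  # unplaced
  m <- merge_placements(dec, all_scaffolds = c("a", "b", "c", "d", "e"))
  expect_equal(m$table$scaffold_id, c("a", "b", "c"))
  expect_equal(m$table$position, 1:3)
  expect_setequal(m$unplaced, c("d", "e"))
  expect_setequal(c(m$table$scaffold_id, m$unplaced),
                  c("a", "b", "c", "d", "e"))

  ov <- data.frame(scaffold_id = "c", chrom = "1", position = 1L,
                   orientation = "-", stringsAsFactors = FALSE)
  m2 <- merge_placements(dec, override = ov,
                         all_scaffolds = c("a", "b", "c", "d", "e"))
  expect_equal(m2$table$scaffold_id, c("c", "a", "b"))
  expect_equal(m2$table$orientation[1], "-")
  expect_equal(m2$table$conflicts[1], "override")

  ov_bad <- data.frame(scaffold_id = "zz", chrom = "1", position = 1L,
                       orientation = "+", stringsAsFactors = FALSE)
  expect_error(merge_placements(dec, override = ov_bad), "unknown scaffold")

  ## empty evidence: everything unplaced
  m0 <- merge_placements(placement_row(character(0)),
                         all_scaffolds = c("x", "y"))
  expect_equal(nrow(m0$table), 0L)
  expect_setequal(m0$unplaced, c("x", "y"))
})

test_that("marker and block evidence interleave through shared anchors", {
  dec <- rbind(
    placement_row("m1", chrom = "1", tier = 1L, orientation = "+",
                  marker_key = 10, block_order = 1, within_key = 100),
    placement_row("m2", chrom = "1", tier = 1L, orientation = "+",
                  marker_key = 20, block_order = 1, within_key = 300),
    placement_row("b1", chrom = "1", tier = 2L, orientation = "+",
                  block_order = 1, within_key = 200))
  m <- merge_placements(dec)
  expect_equal(m$table$scaffold_id, c("m1", "b1", "m2"))
})

test_that("AGP construction and chromosome assembly round-trip", {
  set.seed(12)
  s <- c(sa = random_dna(1000), sb = random_dna(1000))
  tab <- data.frame(chrom = "2a", position = 1:2,
                    scaffold_id = c("sa", "sb"),
                    orientation = c("+", "-"), tier = 1L, conflicts = "",
                    stringsAsFactors = FALSE)
  agp <- build_agp(tab, nchar(s), gap_length = 100L)
  expect_equal(nrow(agp), 3L)
  expect_equal(agp$component_type, c("W", "N", "W"))
  expect_equal(max(agp$object_end), 2100L)

  chr <- build_chromosomes(agp, s)
  expect_equal(names(chr), "chr2a")
  expect_equal(nchar(chr[["chr2a"]]), 2100L)
  ## minus component equals the reverse complement of its source
  expect_equal(substr(chr[["chr2a"]], 1101, 2100), rc(s[["sb"]]))
  ## coordinate round trip: every W row reproduces its oriented scaffold
  for (i in which(agp$component_type == "W")) {
    piece <- substr(chr[[agp$object[i]]], agp$object_beg[i],
                    agp$object_end[i])
    src <- s[[agp$component_id[i]]]
    expect_identical(piece, if (agp$orientation[i] == "-") rc(src) else src)
  }
  expect_error(build_agp(tab, nchar(s)[1]), "missing scaffold length")
})

test_that("tier bookkeeping: one decision per scaffold, placed or unplaced", {
  pl <- study_pipeline(TRUE)$placement
  w <- study_world()
  expect_equal(anyDuplicated(pl$decisions$scaffold_id), 0L)
  all_ids <- c(pl$table$scaffold_id, pl$unplaced)
  expect_equal(anyDuplicated(all_ids), 0L)
  ## every post-break scaffold appears exactly once
  cur <- study_pipeline(TRUE)$curation
  expect_setequal(all_ids, names(cur$scaffolds))
  ## tier monotonicity: scaffolds placed by markers are not re-placed later
  t1 <- pl$decisions$scaffold_id[pl$decisions$tier == 1L &
                                 pl$decisions$placed]
  expect_true(all(pl$table$tier[pl$table$scaffold_id %in% t1] == 1L))
})
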