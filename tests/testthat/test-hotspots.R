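test_that("indel loci are placed by a reference-cursor CIGAR walk", {
  expect_equal(indel_loci(101, "5M2D5M")[, c("start", "end", "op")],
               data.frame(start = 105L, end = 107L, op = "D",
                          stringsAsFactors = FALSE))
  expect_equal(indel_loci(101, "3M1I4M")[, c("start", "end", "op")],
               data.frame(start = 103L, end = 104L, op = "I",
                          stringsAsFactors = FALSE))
  expect_equal(nrow(indel_loci(101, "100M")), 0L)
  # soft clip consumes no reference
  expect_equal(indel_loci(1, "2S3M1D3M")[, c("start", "end")],
               data.frame(start = 3L, end = 4L))
  expect_error(indel_loci(10, "*"), "CIGAR")
  # N advances the cursor but is only evidence when asked
  expect_equal(nrow(indel_loci(1, "5M10N5M")), 0L)
  expect_equal(indel_loci(1, "5M10N5M", include_N = TRUE)$start, 5L)
  expect_equal(indel_loci(1, "5M10N2D3M")$start, 15L)
})

hot_rec <- function(qname, pos, cigar, flag = 0L, contig = "c") {
  qspan <- query_span(parse_cigar(cigar))
  data.frame(qname = qname, flag = as.integer(flag), rname = contig,
             pos = as.integer(pos), mapq = 60L, cigar = cigar, rnext = "*",
             pnext = "0", tlen = "0", seq = strrep("A", max(qspan, 1L)),
             qual = strrep("I", max(qspan, 1L)), tags = "",
             stringsAsFactors = FALSE)
}

test_that("hotspots require min_reads support and pad-then-merge", {
  two <- rbind(hot_rec("a", 101, "5M2D5M"), hot_rec("b", 103, "3M2D5M"))
  got <- collect_hotspots(two, padding = 0, min_reads = 2)
  expect_equal(region_df(got),
               data.frame(contig = "c", start = 105L, end = 107L,
                          stringsAsFactors = FALSE))
  one <- hot_rec("a", 101, "5M2D5M")
  expect_equal(nrow(collect_hotspots(one, padding = 0, min_reads = 2)), 0L)
  # loci [10,11) and [13,14), padding 2 -> merged [8,16)
  pair <- rbind(hot_rec("a", 6, "5M1D5M"), hot_rec("b", 9, "5M1D5M"))
  expect_equal(region_df(collect_hotspots(pair, padding = 2, min_reads = 1)),
               data.frame(contig = "c", start = 8L, end = 16L,
                          stringsAsFactors = FALSE))
})

test_that("padding clamps at zero and at the contig length", {
  r <- hot_rec("a", 2, "1M1D5M")  # deletion at [2,3)
  got <- collect_hotspots(r, padding = 10, min_reads = 1,
                          contig_lengths = c(c = 8L))
  expect_equal(region_df(got),
               data.frame(contig = "c", start = 0L, end = 8L,
                          stringsAsFactors = FALSE))
})

test_that("duplicates and secondary records are excluded by default", {
  dup <- hot_rec("d", 101, "5M2D5M", flag = 1024L)
  sec <- hot_rec("s", 101, "5M2D5M", flag = 256L)
  expect_equal(nrow(collect_hotspots(rbind(dup, sec), padding = 0)), 0L)
  got <- collect_hotspots(dup, padding = 0, include_duplicates = TRUE)
  expect_equal(got$start, 105L)
})

test_that("hotspot extraction equals the per-base pileup oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    recs <- random_read_records(120, contig_len = 9000L)
    for (params in list(c(1, 0), c(2, 0), c(1, 10), c(2, 25))) {
      got <- collect_hotspots(recs, padding = params[2],
                              min_reads = params[1])
      expect_equal(region_df(got),
                   oracle_hotspots(recs, min_reads = params[1],
                                   padding = params[2]))
    }
  }
})

test_that("planted indel loci are recovered exactly and nothing else", {
  ref <- make_reference(c(cA = 8000L, cB = 6000L, cC = 5000L), 17)
  set.seed(17)
  loci <- data.frame(
    contig = rep(c("cA", "cB", "cC"), c(20, 15, 15)),
    pos0 = c(sample(seq(200, 7500, by = 300), 20),
             sample(seq(200, 5700, by = 300), 15),
             sample(seq(200, 4500, by = 280), 15)),
    type = sample(c("I", "D"), 50, replace = TRUE),
    len = sample(1:6, 50, replace = TRUE),
    n_reads = 2L)
  sim <- simulate_alignments(ref, list(indels = loci), 17)
  truth <- sim$manifest$indel_loci
  for (padding in c(0L, 10L)) {
    for (min_reads in c(1L, 2L)) {
      got <- collect_hotspots(sim$sam, padding = padding,
                              min_reads = min_reads,
                              contig_lengths = ref$lengths)
      # every planted locus covered
      for (i in seq_len(nrow(truth))) {
        hit <- restrict_regions(
          region_set(truth$contig[i], truth$start[i], truth$end[i]), got)
        expect_equal(nrow(hit), 1L)
        ov <- got[got$contig == truth$contig[i] &
                    got$start <= truth$start[i] & got$end >= truth$end[i], ]
        expect_gte(nrow(ov), 1L)
      }
      # nothing outside planted loci +/- padding
      allowed <- merge_regions(region_set(truth$contig,
                                          pmax(truth$start - padding, 0L),
                                          truth$end + padding))
      for (i in seq_len(nrow(got))) {
        cover <- allowed[allowed$contig == got$contig[i] &
                           allowed$start <= got$start[i] &
                           allowed$end >= got$end[i], ]
        expect_gte(nrow(cover), 1L)
      }
    }
  }
})

test_that("hotspot base set is monotone in min_reads and padding", {
  set.seed(9)
  recs <- random_read_records(80, contig_len = 8000L)
  bases <- function(rs) sum(rs$end - rs$start)
  b1 <- bases(collect_hotspots(recs, padding = 0, min_reads = 1))
  b2 <- bases(collect_hotspots(recs, padding = 0, min_reads = 2))
  b3 <- bases(collect_hotspots(recs, padding = 0, min_reads = 3))
  expect_true(b1 >= b2 && b2 >= b3)
  p0 <- bases(collect_hotspots(recs, padding = 0))
  p5 <- bases(collect_hotspots(recs, padding = 5))
  p20 <- bases(collect_hotspots(recs, padding = 20))
  expect_true(p0 <= p5 && p5 <= p20)
})

test_that("hotspot output is sorted, non-overlapping and merge-stable", {
  set.seed(3)
  recs <- random_read_records(100, contig_len = 7000L)
  got <- collect_hotspots(recs, padding = 8)
  expect_false(is.unsorted(got$start))
  expect_true(all(got$start[-1] > got$end[-nrow(got)]))
  expect_equal(region_df(merge_regions(got)), region_df(got))
})
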