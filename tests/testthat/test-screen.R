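scr_rec <- function(qname, flag, rname = "*", pos = 0L, cigar = "*") {
  qspan <- if (cigar == "*") 10L else query_span(parse_cigar(cigar))
  data.frame(qname = qname, flag = as.integer(flag), rname = rname,
             pos = as.integer(pos), mapq = 60L, cigar = cigar, rnext = "*",
             pnext = "0", tlen = "0", seq = strrep("A", qspan),
             qual = strrep("I", qspan), tags = "", stringsAsFactors = FALSE)
}

test_that("host subtraction partitions reads by the primary mapped flag", {
  recs <- rbind(
    do.call(rbind, lapply(1:9, function(i)
      scr_rec(paste0("h", i), 0L, "host", i * 100L, "10M"))),
    scr_rec("n1", 4L))
  sub <- subtract_host(sam_object(recs))
  expect_equal(unname(sub$counts), c(9L, 1L))
  all_unm <- sam_object(rbind(scr_rec("a", 4L), scr_rec("b", 4L)))
  expect_equal(subtract_host(all_unm)$counts[["nonhost"]], 2L)
})

test_that("mates of a pair are classified independently", {
  recs <- rbind(scr_rec("p", 1L + 64L, "host", 100L, "10M"),
                scr_rec("p", 1L + 128L + 4L))
  sub <- subtract_host(sam_object(recs))
  expect_equal(sub$host, "p\r1")
  expect_equal(sub$nonhost, "p\r2")
})

test_that("per-genome hits count reads and union covered bases", {
  lens <- c(gA = 10L)
  recs <- rbind(scr_rec("r1", 0L, "gA", 1L, "5M"),
                scr_rec("r2", 0L, "gA", 4L, "5M"))
  hits <- summarize_hits(sam_object(recs), lens)
  expect_equal(hits$read_count, 2L)
  expect_equal(hits$covered_bases, 8L)
  one <- summarize_hits(sam_object(scr_rec("r", 0L, "gB", 1L, "95M")),
                        c(gB = 1000L))
  expect_equal(one$covered_bases, 95L)
  expect_equal(one$breadth_fraction, 0.095)
  # genomes with zero reads are omitted; unknown contigs are an error
  expect_equal(nrow(summarize_hits(sam_object(scr_rec("r", 4L)),
                                   c(gA = 10L))), 0L)
  expect_error(summarize_hits(sam_object(scr_rec("r", 0L, "gX", 1L, "5M")),
                              c(gA = 10L)), "gX")
})

test_that("deletion gaps inside an alignment do not count as covered", {
  hits <- summarize_hits(sam_object(scr_rec("r", 0L, "g", 1L, "5M3D5M")),
                         c(g = 50L))
  expect_equal(hits$covered_bases, 10L)
})

test_that("secondary alignments count only with count_secondary", {
  recs <- rbind(scr_rec("r", 0L, "gA", 1L, "10M"),
                scr_rec("r", 256L, "gB", 1L, "10M"))
  lens <- c(gA = 100L, gB = 100L)
  hits <- summarize_hits(sam_object(recs), lens)
  expect_equal(hits$genome_id, "gA")
  hits2 <- summarize_hits(sam_object(recs), lens, count_secondary = TRUE)
  expect_equal(sort(hits2$genome_id), c("gA", "gB"))
})

test_that("the read-class partition is exact with correct proportions", {
  mix <- simulate_microbial_mixture(
    c(vA = 3000L, vB = 2000L), data.frame(genome_id = c("vA", "vB"),
                                          n_reads = c(3L, 2L)),
    7, n_unknown = 4L, n_human = 91L)
  sc <- screen_reads(mix$host_sam, mix$microbe_sam, mix$lengths)
  expect_equal(sc$n_total, 100L)
  expect_equal(sc$n_human + sc$n_microbial + sc$n_unknown, sc$n_total)
  expect_equal(unname(sc$proportions), c(0.91, 0.05, 0.04))
  expect_equal(sum(sc$proportions), 1)
  # no database hits: unknown equals nonhost
  mix0 <- simulate_microbial_mixture(c(vA = 3000L),
                                     data.frame(genome_id = character(0),
                                                n_reads = integer(0))[0, ],
                                     7, n_unknown = 5L, n_human = 10L)
  sc0 <- screen_reads(mix0$host_sam, mix0$microbe_sam, mix0$lengths)
  expect_equal(sc0$n_unknown, 5L)
  expect_equal(sc0$n_microbial, 0L)
  # degenerate empty input
  empty <- sam_object(scr_rec("x", 0L, "g", 1L, "5M")[0, ])
  sc_e <- screen_reads(empty, empty, c(vA = 3000L))
  expect_equal(sc_e$n_total, 0L)
  expect_equal(sum(sc_e$proportions), 0)
})

test_that("a read claimed by host and database passes is an error", {
  host <- sam_object(scr_rec("r", 0L, "host", 1L, "10M"))
  microbe <- sam_object(scr_rec("r", 0L, "gA", 1L, "10M"))
  expect_error(screen_reads(host, microbe, c(gA = 100L, host = 1000L)),
               "both host and microbial")
})

test_that("planted mixtures are recovered exactly against the manifest", {
  plan <- data.frame(genome_id = c("gA", "gB", "gC"),
                     n_reads = c(100L, 10L, 1L))
  mix <- simulate_microbial_mixture(c(gA = 9000L, gB = 5000L, gC = 2000L),
                                    plan, 19)
  hits <- summarize_hits(mix$microbe_sam, mix$lengths)
  expect_equal(hits$genome_id, c("gA", "gB", "gC"))
  expect_equal(hits$read_count, c(100L, 10L, 1L))
  for (g in hits$genome_id) {
    expect_equal(hits$covered_bases[hits$genome_id == g],
                 mix$manifest$genomes[[g]]$covered_bases)
    expect_equal(hits$covered_bases[hits$genome_id == g],
                 oracle_covered_bases(mix$microbe_sam$records, g,
                                      mix$lengths[[g]]))
  }
})

test_that("top hits rank by read count with lexicographic ties and log10", {
  hits <- data.frame(genome_id = c("A", "B", "C"),
                     genome_length = c(100L, 100L, 100L),
                     read_count = c(5L, 9L, 9L),
                     covered_bases = c(10L, 10L, 10L),
                     breadth_fraction = 0.1, stringsAsFactors = FALSE)
  top <- top_hits(hits, n = 2)
  expect_equal(top$genome_id, c("B", "C"))
  expect_equal(nrow(top_hits(hits, n = 10)), 3L)
  hits$read_count <- c(1000L, 1L, 1L)
  expect_equal(top_hits(hits, 1)$log10_reads, 3)
  # ranking is a truncation of a permutation of the input
  expect_setequal(top_hits(hits, 10)$genome_id, hits$genome_id)
})
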