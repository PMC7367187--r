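gff3_lines <- function(rows) {
  c("##gff-version 3", rows)
}

write_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

test_that("GFF3 and GTF dialects parse to identical transcripts", {
  gff <- write_tmp(gff3_lines(c(
    "chr1\tsrc\tgene\t1\t300\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t1\t300\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\tsrc\texon\t1\t100\t.\t+\t.\tParent=t1",
    "chr1\tsrc\texon\t201\t300\t.\t+\t.\tParent=t1")), ".gff3")
  gtf <- write_tmp(c(
    paste0("chr1\tsrc\texon\t1\t100\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "t1";'),
    paste0("chr1\tsrc\texon\t201\t300\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "t1";')), ".gtf")
  a <- parse_annotation(gff, "exon")
  b <- parse_annotation(gtf, "exon")
  expect_length(a, 1L)
  expect_equal(nrow(a$t1$features), 2L)
  expect_equal(a$t1$features[, c("kind", "start", "stop")],
               b$t1$features[, c("kind", "start", "stop")])
  expect_equal(a$t1$gene_id, b$t1$gene_id)
  expect_equal(a$t1$strand, b$t1$strand)
})

test_that("features without transcript attribution are skipped with a warning", {
  gff <- write_tmp(gff3_lines(c(
    "chr1\tsrc\tgene\t1\t300\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t1\t300\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\tsrc\texon\t1\t100\t.\t+\t.\tParent=t1",
    "chr1\tsrc\texon\t201\t300\t.\t+\t.\tID=orphan")), ".gff3")
  expect_warning(txs <- parse_annotation(gff, "exon"),
                 "without transcript attribution")
  expect_length(txs, 1L)
  expect_equal(nrow(txs$t1$features), 1L)
})

test_that("malformed annotation lines raise an error naming the line", {
  gff <- write_tmp(gff3_lines(c(
    "chr1\tsrc\texon\t1\t100\t.\t+\t.\tParent=t1",
    "chr1\tsrc\texon\t201")), ".gff3")
  expect_error(parse_annotation(gff, "exon"), "line 3")
})

test_that("longest isoform maximises summed feature length, ties lexicographic", {
  a <- tx("txA", "g", "+", "exon", c(1, 301), c(250, 550))    # 500 nt
  b <- tx("txB", "g", "+", "exon", 1, 300)                    # 300 nt
  expect_equal(select_longest_isoform(list(a, b))$transcript_id, "txA")
  t2 <- tx("tx2", "g", "+", "exon", 1, 400)
  t9 <- tx("tx9", "g", "+", "exon", 101, 500)
  expect_equal(select_longest_isoform(list(t9, t2))$transcript_id, "tx2")
  expect_error(select_longest_isoform(list()), "empty")

  set.seed(7)
  for (rep in 1:20) {
    iso <- lapply(1:5, function(i) {
      n <- sample(1:4, 1)
      starts <- cumsum(sample(50:200, n)) + (1:n) * 500
      tx(sprintf("tx%02d", i), "g", "+", "exon", starts,
         starts + sample(20:400, n))
    })
    totals <- vapply(iso, function(t) sum(t$features$stop -
                                          t$features$start + 1), numeric(1))
    best_ids <- vapply(iso, `[[`, "", "transcript_id")[
      totals == max(totals)]
    expect_equal(select_longest_isoform(iso)$transcript_id,
                 sort(best_ids)[1])
  }
})

test_that("intron extraction recovers coordinates, termini and ranks", {
  set.seed(11)
  chr <- rand_dna(400)
  genome <- c(chr1 = chr)
  plus <- tx("t1", "g1", "+", "exon", c(1, 201), c(100, 300))
  ip <- extract_introns(plus, genome)
  expect_equal(nrow(ip), 1L)
  expect_equal(c(ip$start, ip$stop, ip$length), c(101, 200, 100))
  expect_equal(ip$dnt_5, substr(chr, 101, 102))
  expect_equal(ip$dnt_3, substr(chr, 199, 200))
  expect_equal(ip$full_seq, substr(chr, 101, 200))
  expect_equal(ip$intron_id, "asm:chr1:101:200:+")

  minus <- tx("t1m", "g1", "-", "exon", c(1, 201), c(100, 300))
  im <- extract_introns(minus, genome)
  expect_equal(c(im$start, im$stop), c(101, 200))
  expect_equal(im$rank, 1)
  expect_equal(im$full_seq, rc(substr(chr, 101, 200)))
  expect_equal(im$dnt_5, rc(substr(chr, 199, 200)))
  expect_equal(im$dnt_3, rc(substr(chr, 101, 102)))

  three <- tx("t3", "g1", "+", "exon", c(1, 151, 301), c(100, 250, 400))
  i3 <- extract_introns(three, genome)
  expect_equal(i3$rank, c(1, 2))
  expect_equal(i3$start, c(101, 251))
  three_m <- tx("t3m", "g1", "-", "exon", c(1, 151, 301), c(100, 250, 400))
  i3m <- extract_introns(three_m, genome)
  expect_equal(i3m$rank, c(2, 1))  # 5'-most intron is the rightmost gap
})

test_that("abutting features emit no intron; overlapping features error", {
  genome <- c(chr1 = rand_dna(300))
  abut <- tx("t1", "g1", "+", "exon", c(1, 101), c(100, 200))
  expect_equal(nrow(extract_introns(abut, genome)), 0L)
  expect_error(tx("t2", "g1", "+", "exon", c(1, 90), c(100, 200)),
               "overlapping")
})

test_that("motif windows follow the -3..+9 and -55..-5 conventions", {
  set.seed(12)
  chr <- rand_dna(600)
  genome <- c(chr1 = chr)
  t1 <- tx("t1", "g1", "+", "exon", c(1, 301), c(100, 400))  # intron 101-300
  ii <- extract_introns(t1, genome)
  expect_equal(nchar(ii$seq_5ss), 12L)
  expect_equal(ii$seq_5ss, substr(chr, 98, 109))  # -3..+9 around base 101
  L <- ii$length
  expect_equal(nchar(ii$seq_bps_region), 51L)
  expect_equal(ii$seq_bps_region,
               substr(ii$full_seq, L - 54, L - 4))
  # short intron: region truncated away from the 5' splice site
  t2 <- tx("t2", "g2", "+", "exon", c(1, 141), c(100, 240))  # 40 nt intron
  i2 <- extract_introns(t2, genome)
  expect_false(i2$too_short)
  expect_equal(i2$bps_region_start, 10L)
  expect_equal(i2$seq_bps_region, substr(i2$full_seq, 10, 36))
  # sub-30 nt introns are flagged and carry no windows
  t3 <- tx("t3", "g3", "+", "exon", c(1, 121), c(100, 220))  # 20 nt intron
  i3 <- extract_introns(t3, genome)
  expect_true(i3$too_short)
  expect_true(is.na(i3$seq_5ss))
  # 5' splice-site window is N-padded at the chromosome edge
  t4 <- tx("t4", "g4", "+", "exon", c(1, 103), c(2, 300))
  i4 <- extract_introns(t4, genome)
  expect_equal(substr(i4$seq_5ss, 1, 1), "N")
})

test_that("phase is the upstream CDS length mod 3", {
  t6 <- tx("t", "g", "+", "CDS", c(1, 101), c(6, 200))
  expect_equal(compute_phase(t6, 1), 0L)
  t7 <- tx("t", "g", "+", "CDS", c(1, 101), c(7, 200))
  expect_equal(compute_phase(t7, 1), 1L)
  t8 <- tx("t", "g", "+", "CDS", c(1, 101), c(8, 200))
  expect_equal(compute_phase(t8, 1), 2L)
  expect_true(is.na(compute_phase(tx("t", "g", "+", "exon", 1, 6), 1)))
  expect_error(compute_phase(t6, 2), "out of range")

  # concatenation oracle on random multi-CDS transcripts, both strands
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(3:6, 1)
    lens <- sample(10:100, n)
    starts <- cumsum(c(1, lens[-n] + sample(50:100, n - 1)))
    strand <- sample(c("+", "-"), 1)
    t <- tx("t", "g", strand, "CDS", starts, starts + lens - 1)
    ord <- if (strand == "+") seq_len(n) else rev(seq_len(n))
    for (j in seq_len(n - 1)) {
      expect_equal(compute_phase(t, j),
                   as.integer(sum(lens[ord][seq_len(j)]) %% 3))
    }
  }
})

test_that("merge_runs unions keys with CDS records winning", {
  genome <- c(chr1 = rand_dna(1200))
  cds <- extract_introns(tx("t1", "g1", "+", "CDS", c(1, 201), c(100, 300)),
                         genome)
  exn <- rbind(
    extract_introns(tx("t1", "g1", "+", "exon", c(1, 201), c(100, 300)),
                    genome),
    extract_introns(tx("t2", "g2", "+", "exon", c(501, 701), c(600, 800)),
                    genome))
  merged <- merge_runs(cds, exn)
  expect_equal(nrow(merged), 2L)
  shared <- merged[merged$start == 101, ]
  expect_equal(shared$defined_by, "CDS")
  expect_false(is.na(shared$phase))
  utr <- merged[merged$start == 601, ]
  expect_equal(utr$defined_by, "exon")
  expect_true(is.na(utr$phase))

  # |union of keys| property on random overlapping sets
  set.seed(31)
  for (rep in 1:10) {
    mk <- function(n) {
      s <- sample(seq(1, 5000, 100), n)
      data.frame(chrom = "chr1", start = s, stop = s + 50, strand = "+",
                 defined_by = "x", stringsAsFactors = FALSE)
    }
    a <- mk(8); b <- mk(8)
    key <- function(d) paste(d$chrom, d$start, d$stop, d$strand)
    expect_equal(nrow(merge_runs(a, b)),
                 length(union(key(a), key(b))))
  }
})

test_that("abbreviated rendering round-trips against the source sequence", {
  set.seed(41)
  chr <- rand_dna(500)
  genome <- c(chr1 = chr)
  t1 <- tx("t1", "g1", "+", "exon", c(1, 301), c(100, 400))
  ii <- extract_introns(t1, genome)
  pw <- fixture_pwms()
  b <- best_bps(ii, pw$u12_bps,
                consensus_pwm("AAAAAAAAAAAA", 0.25, intron_class = "U2",
                              motif = "BPS"))
  s <- format_abbreviated(ii, b)
  p <- parse_abbreviated(s)
  expect_equal(p$upstream_exon, substr(chr, 95, 100))
  expect_equal(p$intron_5p, substr(ii$full_seq, 1, 10))
  expect_equal(p$bps, b$motif_seq)
  expect_equal(p$intron_3p, substr(ii$full_seq, ii$length - 4, ii$length))
  expect_equal(p$downstream_exon, substr(chr, 301, 306))
  expect_equal(p$dnt_5, ii$dnt_5)
  expect_equal(p$dnt_3, ii$dnt_3)
  # short intron falls back to the full sequence between bars
  t2 <- tx("t2", "g2", "+", "exon", c(1, 121), c(100, 220))
  i2 <- extract_introns(t2, genome)
  s2 <- format_abbreviated(i2, NULL)
  expect_match(s2, i2$full_seq, fixed = TRUE)
})

test_that("strand symmetry: mirrored genome and annotation give identical sequences", {
  set.seed(51)
  for (rep in 1:5) {
    L <- 900
    chr <- rand_dna(L)
    starts <- c(1, 201, 501)
    stops <- c(100, 400, 700)
    fwd <- extract_introns(tx("t", "g", "+", "CDS", starts, stops),
                           c(chr1 = chr))
    # mirror: reverse-complement the chromosome, flip coordinates
    m_starts <- sort(L - stops + 1)
    m_stops <- sort(L - starts + 1)
    rev <- extract_introns(tx("t", "g", "-", "CDS", m_starts, m_stops),
                           c(chr1 = rc(chr)))
    rev <- rev[order(rev$rank), ]
    fwd <- fwd[order(fwd$rank), ]
    for (col in c("full_seq", "seq_5ss", "seq_bps_region",
                  "upstream_flank", "downstream_flank", "dnt_5", "dnt_3",
                  "length", "rank", "phase")) {
      expect_equal(rev[[col]], fwd[[col]], info = col)
    }
  }
})

test_that("exon-intron-exon concatenation reconstructs the genomic substring", {
  set.seed(61)
  chr <- rand_dna(1000)
  genome <- c(chr1 = chr)
  t1 <- tx("t", "g", "+", "exon", c(11, 301, 601), c(150, 450, 800))
  ii <- extract_introns(t1, genome)
  expect_equal(paste0(substr(chr, 11, 150), ii$full_seq[1],
                      substr(chr, 301, 450)),
               substr(chr, 11, 450))
  expect_true(all(ii$length >= 1))
})

test_that("intron table output carries the database columns", {
  set.seed(71)
  genome <- c(chr1 = rand_dna(600))
  ii <- extract_introns(tx("t1", "g1", "+", "CDS", c(1, 301), c(100, 400)),
                        genome)
  path <- tempfile(fileext = ".tsv")
  write_intron_table(ii, path)
  tab <- utils::read.delim(path)
  expect_setequal(
    names(tab),
    c("intron_id", "score", "class", "chrom", "start", "stop", "length",
      "strand", "rank", "phase", "terminal_dinucleotides",
      "upstream_flank", "terminus_3p", "downstream_flank", "full_seq",
      "gene_id", "transcript_id"))
  expect_equal(tab$length, ii$length)
  expect_equal(nchar(tab$terminus_3p), 40L)
})
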