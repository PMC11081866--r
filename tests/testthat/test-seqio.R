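test_that("FASTQ round-trip is lossless for ids, bases and qualities", {
  set.seed(42)
  n <- 100
  reads <- data.frame(
    id = sprintf("read_%03d", 1:n),
    seq = vapply(1:n, function(i) random_dna(sample(50:150, 1)), character(1)),
    stringsAsFactors = FALSE)
  reads$qual <- vapply(nchar(reads$seq), function(L) {
    phred_encode(sample(2:40, L, replace = TRUE))
  }, character(1))
  fq <- tempfile(fileext = ".fastq")
  write_fastq(reads, fq)
  back <- read_fastq(fq)
  expect_identical(back$id, reads$id)
  expect_identical(back$seq, reads$seq)
  expect_identical(back$qual, reads$qual)
  expect_identical(phred_decode(back$qual[1])[[1]],
                   utf8ToInt(reads$qual[1]) - 33L)

  # gzip round-trip is transparent
  fqz <- tempfile(fileext = ".fastq.gz")
  write_fastq(reads, fqz)
  expect_identical(read_fastq(fqz)$seq, reads$seq)
})

test_that("FASTQ parsing agrees with the Biostrings reader", {
  set.seed(7)
  reads <- data.frame(id = sprintf("r%d", 1:20),
                      seq = vapply(1:20, function(i) random_dna(80), character(1)),
                      stringsAsFactors = FALSE)
  reads$qual <- strrep("I", 80)
  fq <- tempfile(fileext = ".fastq")
  write_fastq(reads, fq)
  bs <- Biostrings::readDNAStringSet(fq, format = "fastq")
  expect_identical(unname(as.character(bs)), reads$seq)
  expect_identical(names(bs), reads$id)
})

test_that("malformed FASTQ records are rejected with their record index", {
  fq <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII",
               "@r2", "ACGTAC", "+", "III"), fq)    # short quality line
  expect_error(read_fastq(fq), "record 2", class = "bequant_parse_error")

  writeLines(c("@r1", "ACGT", "IIII"), fq)          # missing separator
  expect_error(read_fastq(fq), class = "bequant_parse_error")

  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "AC"), fq)  # truncated
  expect_error(read_fastq(fq), class = "bequant_parse_error")

  writeLines(character(0), fq)                      # empty file, empty stream
  expect_identical(nrow(read_fastq(fq)), 0L)

  writeLines(c("@r1", "ACGTN", "+", "IIIII"), fq)   # N is retained
  expect_identical(read_fastq(fq)$seq, "ACGTN")
})

test_that("amplicon spec validation enforces geometry invariants", {
  spec <- example_amplicon_spec()
  ps <- spec$protospacers

  # matching protospacer accepted (construction itself)
  expect_s3_class(spec, "amplicon_spec")

  # protospacer shifted by one rejected
  expect_error(
    amplicon_spec("x", spec$reference,
                  transform(ps, start = start + 1L), spec$target_adenine),
    class = "bequant_spec_error")

  # reverse-strand protospacer equal to the reverse complement of the slice
  rc_ps <- transform(ps, seq = revcomp(seq), strand = "-")
  spec_rc <- amplicon_spec("x", spec$reference, rc_ps,
                           target_adenine = 110L)  # a T on the reference
  expect_identical(spec_rc$proto_strand, "-")

  # target position that is not an A on the protospacer strand
  expect_error(
    amplicon_spec("x", spec$reference, ps, target_adenine = 106L),
    "not an A", class = "bequant_spec_error")

  # window outside the reference
  expect_error(
    amplicon_spec("x", spec$reference, ps, spec$target_adenine,
                  quant_window = c(100L, 500L)),
    class = "bequant_spec_error")

  # target outside the quantification window
  expect_error(
    amplicon_spec("x", spec$reference, ps, spec$target_adenine,
                  quant_window = c(110L, 120L)),
    class = "bequant_spec_error")
})

test_that("randomly corrupted specs are always rejected", {
  spec <- example_amplicon_spec()
  ps <- spec$protospacers
  set.seed(99)
  for (i in 1:25) {
    kind <- sample(c("shift", "mutate", "target", "window"), 1)
    expect_error(switch(kind,
      shift = amplicon_spec("x", spec$reference,
                            transform(ps, start = start + sample(c(-5:-1, 1:5), 1)),
                            spec$target_adenine),
      mutate = amplicon_spec("x", spec$reference,
                             transform(ps, seq = mutate_k(seq, 1)),
                             spec$target_adenine),
      target = amplicon_spec("x", spec$reference, ps,
                             target_adenine = sample(c(100, 101, 103, 106, 110), 1)),
      window = amplicon_spec("x", spec$reference, ps, spec$target_adenine,
                             indel_window = c(130L, 140L))),
      class = "bequant_spec_error")
  }
})

test_that("amplicon specs load from YAML, inline or via FASTA reference", {
  spec <- example_amplicon_spec()
  dir <- tempfile(); dir.create(dir)
  fa <- file.path(dir, "ref.fa")
  writeLines(c(">demo_locus", spec$reference), fa)
  yml <- file.path(dir, "locus.yaml")
  yaml::write_yaml(list(
    locus_name = "demo_locus", reference_fasta = "ref.fa",
    protospacers = list(list(label = "sg1", seq = spec$protospacers$seq[1],
                             start = 100L, strand = "+", pam = "TGG")),
    target_adenine = 107L,
    cds = spec$cds), yml)
  loaded <- load_amplicon_spec(yml)
  expect_identical(loaded$reference, spec$reference)
  expect_identical(loaded$quant_window, spec$quant_window)
  expect_identical(loaded$nick_offset, spec$nick_offset)
})

test_that("sample sheets are validated", {
  dir <- tempfile(); dir.create(dir)
  fq <- file.path(dir, "a.fastq")
  writeLines(c("@r", "ACGT", "+", "IIII"), fq)
  sheet <- file.path(dir, "samples.tsv")
  write.table(data.frame(sample_id = c("s1", "s2"),
                         fastq1 = c("a.fastq", "a.fastq"),
                         locus = "demo_locus"),
              sheet, sep = "\t", quote = FALSE, row.names = FALSE)
  loci <- list(demo_locus = example_amplicon_spec())
  out <- read_sample_sheet(sheet, loci)
  expect_identical(out$sample_id, c("s1", "s2"))

  write.table(data.frame(sample_id = c("s1", "s1"), fastq1 = "a.fastq",
                         locus = "demo_locus"),
              sheet, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_sample_sheet(sheet, loci), "duplicate",
               class = "bequant_spec_error")

  write.table(data.frame(sample_id = "s1", fastq1 = "missing.fastq",
                         locus = "demo_locus"),
              sheet, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_sample_sheet(sheet, loci), "s1",
               class = "bequant_io_error")
})
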