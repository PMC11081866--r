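spec <- example_amplicon_spec()

test_that("adenine numbering covers the combined protospacer interval", {
  idx <- build_adenine_index(spec)
  expect_identical(idx$label, c("A1", "A2", "A3", "A4"))
  expect_identical(idx$ref_offset, c(105L, 107L, 113L, 119L))
  expect_identical(idx$proto_pos, c(6L, 8L, 14L, 20L))

  # a second protospacer shifted by 2 nt extends the union interval
  ps2 <- rbind(spec$protospacers,
               data.frame(label = "sg2", seq = substr(spec$reference, 99, 118),
                          start = 98L, strand = "+", pam = substr(spec$reference, 119, 121)))
  spec2 <- amplicon_spec("two_guides", spec$reference, ps2, 107L)
  idx2 <- build_adenine_index(spec2)
  expect_identical(min(idx2$ref_offset) >= 98L, TRUE)
  expect_identical(idx2$ref_offset, c(105L, 107L, 113L, 119L))  # no A at 98/99

  # opposite strands at one locus are unsupported
  ps_mix <- rbind(spec$protospacers,
                  data.frame(label = "sg3", seq = revcomp(substr(spec$reference, 99, 118)),
                             start = 98L, strand = "-", pam = "NNN"))
  expect_error(build_adenine_index(
    structure(list(protospacers = ps_mix, reference = spec$reference),
              class = "amplicon_spec")),
    class = "bequant_config_error")

  # protospacer without adenines yields an empty index with a warning
  ref_no_a <- paste0(strrep("C", 30), "GCGCGCGTTTGCGCGCGTTG", "TGG", "A",
                     strrep("C", 29))
  spec_no_a <- amplicon_spec("no_a", ref_no_a,
                             data.frame(label = "sg", seq = "GCGCGCGTTTGCGCGCGTTG",
                                        start = 30L, strand = "+", pam = "TGG"),
                             target_adenine = 53L, quant_window = c(30L, 54L))
  expect_warning(idx0 <- build_adenine_index(spec_no_a), "no adenines")
  expect_identical(nrow(idx0), 0L)
})

test_that("allele tables partition aligned reads with exact frequencies", {
  truth <- spiked_truth(spec, 0.459, 0.048, 0.002, n = 5000, seed = 31)
  fq <- tempfile(fileext = ".fastq")
  sim <- simulate_reads(spec, truth, fq)
  res <- quantify_fastq(fq, spec, check_rc = FALSE)
  tab <- res$table

  expect_identical(sum(tab$count), attr(tab, "n_aligned"))
  expect_equal(sum(tab$frequency), 1, tolerance = 1e-9)

  # partition property: class counts sum to n_aligned, classes exclusive
  expect_identical(sum(res$summary$class_counts), attr(tab, "n_aligned"))

  # frequencies equal the simulator's label fractions exactly (error-free)
  labfrac <- table(sim$labels$allele) / nrow(sim$labels)
  expect_identical(res$summary$desired_only_rate,
                   unname(labfrac[["desired_only"]]))
  expect_identical(res$summary$nonsynonymous_bystander_rate,
                   unname(labfrac[["bystander"]]))
  expect_identical(res$summary$indel_rate, unname(labfrac[["indel"]]))
})

test_that("all-reference input yields a single wildtype allele and zero rates", {
  reads <- data.frame(id = sprintf("r%d", 1:40), seq = spec$reference,
                      qual = strrep("I", 240), mate = NA_integer_,
                      stringsAsFactors = FALSE)
  aln <- align_reads(reads, spec, check_rc = FALSE)
  tab <- build_allele_table(aln, spec)
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$class, "wildtype")
  expect_equal(tab$frequency, 1)
  expect_equal(desired_only_rate(tab), 0)
  expect_true(all(per_adenine_rates(tab) == 0))
  expect_equal(indel_rate(tab), 0)
})

test_that("desired-only and per-adenine rates follow their definitions", {
  # 30% of reads carry exactly the target A>G, rest wildtype
  edited <- spec$reference
  substr(edited, 108, 108) <- "G"     # offset 107
  reads <- data.frame(id = sprintf("r%d", 1:100),
                      seq = c(rep(edited, 30), rep(spec$reference, 70)),
                      qual = strrep("I", 240), mate = NA_integer_,
                      stringsAsFactors = FALSE)
  tab <- build_allele_table(align_reads(reads, spec, check_rc = FALSE), spec)
  expect_equal(desired_only_rate(tab), 0.30)
  rates <- per_adenine_rates(tab)
  expect_equal(unname(rates["A2"]), 0.30)
  expect_equal(unname(rates["A1"]), 0)

  # an allele editing A3 and A4 at 5% contributes to both positions
  bys <- spec$reference
  substr(bys, 114, 114) <- "G"; substr(bys, 120, 120) <- "G"
  reads2 <- data.frame(id = sprintf("b%d", 1:100),
                       seq = c(rep(bys, 5), rep(spec$reference, 95)),
                       qual = strrep("I", 240), mate = NA_integer_,
                       stringsAsFactors = FALSE)
  tab2 <- build_allele_table(align_reads(reads2, spec, check_rc = FALSE), spec)
  r2 <- per_adenine_rates(tab2)
  expect_equal(unname(r2["A3"]), 0.05)
  expect_equal(unname(r2["A4"]), 0.05)
  expect_equal(unname(r2["A2"]), 0)
  expect_equal(desired_only_rate(tab2), 0)
})

test_that("per-adenine rates equal a brute-force per-read count oracle", {
  truth <- spiked_truth(spec, 0.3, 0.15, 0, n = 3000, seed = 41)
  fq <- tempfile(fileext = ".fastq")
  simulate_reads(spec, truth, fq)
  seqs <- read_fastq(fq)$seq
  res <- quantify_fastq(fq, spec, check_rc = FALSE)
  idx <- build_adenine_index(spec)
  for (k in seq_len(nrow(idx))) {
    off <- idx$ref_offset[k]
    base_at <- substr(seqs, off + 1, off + 1)   # no indels in this mixture
    expect_equal(unname(res$summary$per_adenine_rate[idx$label[k]]),
                 mean(base_at == "G"),
                 info = idx$label[k])
  }
})

test_that("indels are counted only when they overlap the indel window", {
  # 1-bp deletion at the nick: counted
  del_nick <- paste0(substr(spec$reference, 1, spec$nick_offset),
                     substr(spec$reference, spec$nick_offset + 2, 240))
  # deletion far outside the window: not counted
  del_out <- paste0(substr(spec$reference, 1, 30), substr(spec$reference, 32, 240))
  reads <- data.frame(id = sprintf("r%d", 1:60),
                      seq = c(rep(del_nick, 6), rep(del_out, 6),
                              rep(spec$reference, 48)),
                      qual = c(rep(strrep("I", 239), 12), rep(strrep("I", 240), 48)),
                      mate = NA_integer_, stringsAsFactors = FALSE)
  aln <- align_reads(reads, spec, check_rc = FALSE)
  expect_equal(indel_rate(aln, spec), 0.1)
  tab <- build_allele_table(aln, spec)
  expect_equal(indel_rate(tab), 0.1)
  # the outside-window deletion read is wildtype over the window
  expect_identical(sum(tab$count[tab$class == "indel"]), 6L)
})

test_that("display filtering drops below-threshold alleles but keeps stats", {
  edited <- spec$reference
  substr(edited, 108, 108) <- "G"
  bys <- edited
  substr(bys, 114, 114) <- "G"
  reads <- data.frame(
    id = sprintf("r%d", 1:10000),
    seq = c(rep(bys, 19), rep(edited, 20), rep(spec$reference, 9961)),
    qual = strrep("I", 240), mate = NA_integer_, stringsAsFactors = FALSE)
  tab <- build_allele_table(align_reads(reads, spec, check_rc = FALSE), spec)
  filt <- filter_alleles_for_report(tab)       # default 0.002 = 0.20%
  expect_true(0.0019 %in% round(tab$frequency, 4))
  expect_false(any(filt$frequency < 0.002))
  expect_identical(nrow(filt), nrow(tab) - 1L)  # only the 0.0019 row dropped
  # summary statistics always use the unfiltered table
  expect_equal(desired_only_rate(tab), 20 / 10000)
  expect_identical(filter_alleles_for_report(tab, 0)$allele, tab$allele)
  empty <- filter_alleles_for_report(tab, 1.1)
  expect_identical(nrow(empty), 0L)
})

test_that("desired-only rate never exceeds the target adenine rate", {
  set.seed(53)
  for (i in 1:5) {
    truth <- spiked_truth(spec, runif(1, 0, 0.5), runif(1, 0, 0.2),
                          runif(1, 0, 0.05), error = runif(1, 0, 0.01),
                          n = 1000, seed = 100 + i)
    fq <- tempfile(fileext = ".fastq")
    simulate_reads(spec, truth, fq)
    s <- quantify_fastq(fq, spec, check_rc = FALSE)$summary
    expect_lte(s$desired_only_rate, s$per_adenine_rate[["A2"]] + 1e-12)
  }
})

test_that("zero accepted alignments is an explicit error", {
  set.seed(61)
  junk <- data.frame(id = "j", seq = random_dna(240), qual = strrep("I", 240),
                     mate = NA_integer_, stringsAsFactors = FALSE)
  aln <- align_reads(junk, spec, check_rc = FALSE)
  expect_error(build_allele_table(aln, spec), class = "bequant_quant_error")
})
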