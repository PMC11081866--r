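proto <- "GCTCCACACGTTTACGGTGA"

# build a target contig with planted sites at known mismatch counts
plant_site <- function(base_seq, pos, site_seq, pam = "TGG") {
  paste0(substr(base_seq, 1, pos), site_seq, pam,
         substr(base_seq, pos + nchar(site_seq) + nchar(pam) + 1,
                nchar(base_seq)))
}

test_that("planted sites are found at and only at permissive thresholds", {
  set.seed(101)
  bg <- random_dna(3000)
  site3 <- mutate_k(proto, 3)
  seqs <- c(chr1 = plant_site(bg, 500, proto),        # on-target, 0 mm
            chr2 = plant_site(random_dna(3000), 1200, site3))

  hits6 <- find_candidate_sites(seqs, proto, offtarget_params(max_mismatches = 6))
  expect_identical(hits6$mismatches[1], 0L)           # on-target ranks first
  expect_identical(hits6$rank[1], 1L)
  expect_true(any(hits6$contig == "chr2" & hits6$start == 1200 &
                    hits6$mismatches == 3L))

  hits2 <- find_candidate_sites(seqs, proto, offtarget_params(max_mismatches = 2))
  expect_false(any(hits2$contig == "chr2" & hits2$start == 1200))
  expect_true(any(hits2$mismatches == 0L))
})

test_that("a matching spacer with a failing PAM is not reported", {
  set.seed(103)
  bg <- random_dna(2000)
  seqs <- c(good = plant_site(bg, 300, proto, pam = "TGG"),
            bad = plant_site(random_dna(2000), 300, proto, pam = "TTT"))
  hits <- find_candidate_sites(seqs, proto,
                               offtarget_params(max_mismatches = 1,
                                                pam_pattern = "NGN"))
  expect_true(any(hits$contig == "good" & hits$start == 300))
  expect_false(any(hits$contig == "bad" & hits$start == 300))
})

test_that("minus-strand sites are reported with mirrored coordinates", {
  set.seed(107)
  bg <- random_dna(2000)
  fw <- plant_site(bg, 700, proto)
  rc <- revcomp(fw)
  hits_fw <- find_candidate_sites(c(s = fw), proto,
                                  offtarget_params(max_mismatches = 0))
  hits_rc <- find_candidate_sites(c(s = rc), proto,
                                  offtarget_params(max_mismatches = 0))
  expect_identical(nrow(hits_fw), 1L)
  expect_identical(nrow(hits_rc), 1L)
  expect_identical(hits_fw$strand, "+")
  expect_identical(hits_rc$strand, "-")
  expect_identical(hits_rc$start, nchar(fw) - hits_fw$start - nchar(proto))
  expect_identical(hits_rc$site, proto)
})

test_that("ranking is stable under input permutation and top_n truncates", {
  set.seed(109)
  seqs <- setNames(lapply(1:4, function(i) {
    plant_site(random_dna(1500), 200 * i, mutate_k(proto, i))
  }), paste0("c", 1:4))
  seqs <- vapply(seqs, identity, character(1))
  a <- find_candidate_sites(seqs, proto, offtarget_params(max_mismatches = 6))
  b <- find_candidate_sites(rev(seqs), proto, offtarget_params(max_mismatches = 6))
  key <- function(x) paste(x$contig, x$start, x$strand, x$mismatches)
  expect_identical(key(a), key(b))

  expect_identical(nrow(top_n_sites(a, 2)), 2L)
  expect_identical(nrow(top_n_sites(a, 100)), nrow(a))
  expect_identical(top_n_sites(a, 2)$rank, 1:2)
})

test_that("nearby hits are merged keeping the lower-mismatch one", {
  # two overlapping candidate starts 1 bp apart: keep the better one
  set.seed(113)
  bg <- random_dna(1000)
  # plant a perfect site; a 1-shifted window will typically exceed the
  # threshold, so construct an explicit near-duplicate instead
  s <- plant_site(bg, 400, proto)
  hits_all <- find_candidate_sites(c(x = s), proto,
                                   offtarget_params(max_mismatches = 6,
                                                    window_size = 0))
  hits_merged <- find_candidate_sites(c(x = s), proto,
                                      offtarget_params(max_mismatches = 6,
                                                       window_size = 3))
  expect_lte(nrow(hits_merged), nrow(hits_all))
  expect_true(any(hits_merged$start == 400 & hits_merged$mismatches == 0L))
})

test_that("bulged sites are admitted only with allow_gaps", {
  set.seed(127)
  bg <- random_dna(1500)
  bulged <- paste0(substr(proto, 1, 10), substr(proto, 12, 20))  # 1-bp deletion
  s <- plant_site(bg, 600, bulged)
  strict <- find_candidate_sites(c(x = s), proto,
                                 offtarget_params(max_mismatches = 2))
  expect_false(any(strict$start == 600 & strict$gaps > 0))
  gappy <- find_candidate_sites(c(x = s), proto,
                                offtarget_params(max_mismatches = 2,
                                                 allow_gaps = TRUE,
                                                 gap_threshold = 3))
  hit <- gappy[gappy$start == 600, ]
  expect_gte(nrow(hit), 1L)
  expect_identical(hit$gaps[1], 1L)
})

test_that("an empty target set is an error, short protospacers too", {
  expect_error(find_candidate_sites(character(0), proto),
               class = "bequant_offtarget_error")
  expect_error(find_candidate_sites(c(a = "ACGT"), "ACGTACGTACGT"),
               class = "bequant_offtarget_error")
})

test_that("a site-derived amplicon spec feeds the quantifier", {
  set.seed(131)
  on_spec <- example_amplicon_spec()
  bg <- random_dna(2000)
  site_seq <- mutate_k(proto, 2)
  seqs <- c(chr9 = plant_site(bg, 800, site_seq))
  sites <- find_candidate_sites(seqs, proto, offtarget_params(max_mismatches = 4))
  site <- sites[sites$start == 800, ][1, ]
  ospec <- off_target_amplicon_spec(seqs, site, on_spec, flank = 50)
  expect_s3_class(ospec, "amplicon_spec")
  # unedited reads from the site quantify as fully wildtype
  reads <- data.frame(id = sprintf("r%d", 1:20), seq = ospec$reference,
                      qual = strrep("I", nchar(ospec$reference)),
                      mate = NA_integer_, stringsAsFactors = FALSE)
  tab <- build_allele_table(align_reads(reads, ospec, check_rc = FALSE), ospec)
  expect_equal(desired_only_rate(tab), 0)
  expect_equal(indel_rate(tab), 0)
})

test_that("BED-like site export round-trips through read.delim", {
  set.seed(137)
  seqs <- c(c1 = plant_site(random_dna(1000), 300, proto))
  sites <- find_candidate_sites(seqs, proto)
  bed <- tempfile(fileext = ".tsv")
  write_sites_bed(sites, bed)
  back <- read.delim(bed)
  expect_identical(back$start, sites$start)
  expect_identical(back$site, sites$site)
})
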