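#' Construct a ground-truth manifest for read simulation
#'
#' A truth manifest fixes everything the simulator will do: the allele
#' mixture (substitution sets and optional indels with their proportions),
#' the number of reads, the per-base substitution error rate, the quality
#' model, pairedness, and the seed. Identical manifests produce
#' byte-identical FASTQ output.
#'
#' @param alleles list of alleles; each a list with `label`, `subs` (named
#'   character vector, names = 0-based reference offsets, values = alt
#'   base), optional `indel` (list with `position`, `length`,
#'   `type` = `"ins"`/`"del"`, and for insertions optional `bases`), and
#'   `proportion`.
#' @param n_reads number of reads (or read pairs).
#' @param error_rate per-base substitution error probability in `[0, 1)`;
#'   errors substitute uniformly among the three non-template bases.
#' @param qual constant Phred quality, or an integer vector giving a
#'   position-dependent profile (recycled to read length).
#' @param paired simulate perfectly overlapping mate pairs from opposite
#'   strands with independent errors.
#' @param read_length read length; `NULL` means the full allele sequence.
#' @param seed integer seed controlling allele assignment, error positions
#'   and error base choice.
#' @return an object of class `truth_manifest`.
#' @export
truth_manifest <- function(alleles, n_reads, error_rate = 0, qual = 37L,
                           paired = FALSE, read_length = NULL, seed = 1L) {
  props <- vapply(alleles, function(a) a$proportion, numeric(1))
  if (abs(sum(props) - 1) > 1e-9) {
    bq_stop("bequant_truth_error", "allele proportions sum to %.12f, not 1", sum(props))
  }
  if (any(props < 0)) bq_stop("bequant_truth_error", "negative allele proportion")
  if (error_rate < 0 || error_rate >= 1) {
    bq_stop("bequant_truth_error", "error_rate must be in [0, 1)")
  }
  labels <- vapply(alleles, function(a) a$label, character(1))
  if (anyDuplicated(labels)) bq_stop("bequant_truth_error", "duplicate allele labels")
  structure(list(alleles = alleles, n_reads = as.integer(n_reads),
                 error_rate = error_rate, qual = as.integer(qual),
                 paired = isTRUE(paired), read_length = read_length,
                 seed = as.integer(seed),
                 rng = "Mersenne-Twister/Inversion/Rejection"),
            class = "truth_manifest")
}

#' Study-style spiked truth: desired edit, bystander, indel, wildtype
#'
#' Convenience constructor for the canonical validation mixture: a
#' desired-edit-only allele, a bystander allele carrying the desired edit
#' plus one nonsynonymous A-to-G within the protospacer, a 1-bp deletion
#' allele at the nick site, and wildtype filling the remainder. Default
#' proportions mirror in vivo cortex-scale editing (around 46% correction,
#' around 5% bystanders, around 0.1% indels).
#'
#' @param spec an [amplicon_spec()].
#' @param on_target proportion of desired-edit-only reads.
#' @param bystander proportion of reads with desired edit plus a
#'   nonsynonymous bystander A-to-G.
#' @param indel proportion of reads with a 1-bp deletion at the nick site.
#' @param error per-base substitution error rate.
#' @param n number of reads.
#' @param seed integer seed.
#' @inheritParams truth_manifest
#' @return a `truth_manifest`.
#' @export
#' @examples
#' spiked_truth(example_amplicon_spec(), 0.459, 0.048, 0.001, n = 1000)
spiked_truth <- function(spec, on_target = 0.459, bystander = 0.048,
                         indel = 0.001, error = 0, n = 20000L, seed = 1L,
                         paired = FALSE, qual = 37L) {
  total <- on_target + bystander + indel
  if (total > 1 + 1e-12) {
    bq_stop("bequant_truth_error", "proportions sum to %.4f > 1", total)
  }
  tgt <- spec$target_adenine
  g_on_proto <- if (spec$proto_strand == "+") "G" else "C"
  desired <- setNames(g_on_proto, as.character(tgt))

  alleles <- list()
  if (on_target > 0) {
    alleles <- c(alleles, list(list(label = "desired_only", subs = desired,
                                    indel = NULL, proportion = on_target)))
  }
  if (bystander > 0) {
    bys_off <- pick_nonsyn_bystander(spec)
    alleles <- c(alleles, list(list(
      label = "bystander",
      subs = c(desired, setNames(g_on_proto, as.character(bys_off))),
      indel = NULL, proportion = bystander)))
  }
  if (indel > 0) {
    alleles <- c(alleles, list(list(
      label = "indel",
      subs = setNames(character(0), character(0)),
      indel = list(position = spec$nick_offset, length = 1L, type = "del"),
      proportion = indel)))
  }
  wt <- 1 - total
  alleles <- c(alleles, list(list(label = "wildtype",
                                  subs = setNames(character(0), character(0)),
                                  indel = NULL, proportion = wt)))
  truth_manifest(alleles, n_reads = n, error_rate = error, qual = qual,
                 paired = paired, seed = seed)
}

# First non-target adenine (5'->3' on the protospacer strand) whose A->G is
# nonsynonymous under the spec's CDS; falls back to any non-target adenine.
pick_nonsyn_bystander <- function(spec) {
  idx <- build_adenine_index(spec)
  cand <- idx$ref_offset[idx$ref_offset != spec$target_adenine]
  if (!length(cand)) {
    bq_stop("bequant_truth_error", "locus has no non-target adenine for a bystander allele")
  }
  if (!is.null(spec$cds)) {
    g_ref <- if (spec$proto_strand == "+") "G" else "C"
    for (off in cand) {
      call <- annotate_substitution(off, g_ref, spec)
      if (call$consequence %in% c("nonsynonymous", "stop_gained", "stop_lost")) {
        return(off)
      }
    }
  }
  cand[1]
}

# Materialize one allele's full sequence from the reference.
allele_sequence <- function(spec, allele) {
  chars <- strsplit(spec$reference, "", fixed = TRUE)[[1]]
  if (length(allele$subs)) {
    offs <- as.integer(names(allele$subs))
    if (any(offs < 0 | offs >= length(chars))) {
      bq_stop("bequant_truth_error", "substitution offset outside reference")
    }
    chars[offs + 1L] <- toupper(unname(allele$subs))
  }
  if (!is.null(allele$indel)) {
    pos <- allele$indel$position
    len <- allele$indel$length
    if (pos < 0 || pos > length(chars) ||
        (allele$indel$type == "del" && pos + len > length(chars))) {
      bq_stop("bequant_truth_error", "indel position outside reference")
    }
    if (allele$indel$type == "del") {
      chars <- chars[-(pos + seq_len(len))]
    } else {
      ins <- allele$indel$bases
      if (is.null(ins)) ins <- strrep("A", len)
      chars <- append(chars, strsplit(toupper(ins), "", fixed = TRUE)[[1]],
                      after = pos)
    }
  }
  paste(chars, collapse = "")
}

#' Simulate amplicon reads from a truth manifest
#'
#' Draws each read's allele by its proportion, applies per-base
#' substitution errors (uniform over the three non-template bases), and
#' writes Phred+33 FASTQ. In paired mode the two mates cover the same
#' fragment from opposite strands with independent errors. A fixed seed
#' gives byte-identical output.
#'
#' @param spec an [amplicon_spec()].
#' @param truth a [truth_manifest()].
#' @param fastq1 output FASTQ path (read 1 in paired mode).
#' @param fastq2 output path for read 2; required when `truth$paired`.
#' @return invisibly, a list with `files`, `labels` (data frame of
#'   `id`/`allele`, the per-read ground truth), and the echoed `truth`.
#' @export
simulate_reads <- function(spec, truth, fastq1, fastq2 = NULL) {
  stopifnot(inherits(spec, "amplicon_spec"), inherits(truth, "truth_manifest"))
  if (truth$paired && is.null(fastq2)) {
    bq_stop("bequant_truth_error", "paired simulation needs a fastq2 path")
  }
  seqs <- vapply(truth$alleles, function(a) allele_sequence(spec, a), character(1))
  labels_all <- vapply(truth$alleles, function(a) a$label, character(1))
  props <- vapply(truth$alleles, function(a) a$proportion, numeric(1))

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(truth$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")

  n <- truth$n_reads
  lab <- sample(labels_all, n, replace = TRUE, prob = props)
  ids <- sprintf("sim%06d", seq_len(n))

  make_mate <- function(sense = TRUE) {
    # one sequence per read, errors applied per allele group in label order
    out <- character(n)
    for (al in labels_all) {
      sel <- which(lab == al)
      if (!length(sel)) next
      s <- seqs[[match(al, labels_all)]]
      if (!is.null(truth$read_length) && truth$read_length < nchar(s)) {
        s <- if (sense) substr(s, 1L, truth$read_length) else
          substr(s, nchar(s) - truth$read_length + 1L, nchar(s))
      }
      if (!sense) s <- revcomp(s)
      out[sel] <- apply_errors(s, length(sel), truth$error_rate)
    }
    out
  }

  r1 <- make_mate(sense = TRUE)
  quals1 <- vapply(nchar(r1), function(L) {
    phred_encode(rep_len(truth$qual, L))
  }, character(1))

  labels_df <- data.frame(id = ids, allele = lab, stringsAsFactors = FALSE)
  files <- fastq1
  if (truth$paired) {
    r2 <- make_mate(sense = FALSE)
    quals2 <- vapply(nchar(r2), function(L) {
      phred_encode(rep_len(truth$qual, L))
    }, character(1))
    write_fastq(data.frame(id = paste0(ids, "/1"), seq = r1, qual = quals1,
                           stringsAsFactors = FALSE), fastq1)
    write_fastq(data.frame(id = paste0(ids, "/2"), seq = r2, qual = quals2,
                           stringsAsFactors = FALSE), fastq2)
    files <- c(fastq1, fastq2)
  } else {
    write_fastq(data.frame(id = ids, seq = r1, qual = quals1,
                           stringsAsFactors = FALSE), fastq1)
  }
  invisible(list(files = files, labels = labels_df, truth = truth))
}

# Apply iid per-base substitution errors to k copies of template sequence s.
apply_errors <- function(s, k, error_rate) {
  L <- nchar(s)
  if (error_rate == 0 || L == 0) return(rep(s, k))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  m <- matrix(rep(chars, each = k), nrow = k)
  hit <- matrix(stats::runif(k * L) < error_rate, nrow = k)
  nh <- sum(hit)
  if (nh > 0) {
    # uniform choice among the 3 non-template bases; N stays N
    alts <- matrix(c("C", "G", "T",
                     "A", "G", "T",
                     "A", "C", "T",
                     "A", "C", "G"), nrow = 4, byrow = TRUE,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
    orig <- m[hit]
    pick <- sample.int(3L, nh, replace = TRUE)
    sub <- orig
    known <- orig %in% rownames(alts)
    sub[known] <- alts[cbind(match(orig[known], rownames(alts)), pick[known])]
    m[hit] <- sub
  }
  apply(m, 1L, paste, collapse = "")
}

#' Serialize a truth manifest to JSON
#' @param truth a `truth_manifest`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_manifest <- function(truth, path) {
  x <- unclass(truth)
  x$alleles <- lapply(x$alleles, function(a) {
    list(label = a$label,
         subs = if (length(a$subs)) as.list(a$subs) else NULL,
         indel = a$indel, proportion = a$proportion)
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a truth manifest from JSON
#' @param path JSON path written by [write_truth_manifest()].
#' @return a `truth_manifest`.
#' @export
read_truth_manifest <- function(path) {
  x <- jsonlite::read_json(path)
  alleles <- lapply(x$alleles, function(a) {
    subs <- if (is.null(a$subs)) setNames(character(0), character(0)) else
      unlist(a$subs)
    indel <- a$indel
    if (!is.null(indel)) {
      indel$position <- as.integer(indel$position)
      indel$length <- as.integer(indel$length)
    }
    list(label = a$label, subs = subs, indel = indel,
         proportion = as.numeric(a$proportion))
  })
  truth_manifest(alleles, n_reads = as.integer(x$n_reads),
                 error_rate = as.numeric(x$error_rate),
                 qual = as.integer(unlist(x$qual)),
                 paired = isTRUE(x$paired),
                 read_length = if (is.null(x$read_length)) NULL else as.integer(x$read_length),
                 seed = as.integer(x$seed))
}

#' Simulate a phenotype cohort with a planted editing correlation
#'
#' Generates a per-animal table shaped like an in vivo endpoint dataset:
#' genotype strata, editing outcomes, bodyweight, grip strength and beam
#' traverse time. Within the heterozygous stratum, the sample Pearson
#' correlation between the nonsynonymous bystander rate and bodyweight is
#' planted exactly at `r_weight` (residual-orthogonalisation
#' construction), so recovery by [run_report()] can be asserted against a
#' known value. Other phenotypes are uncorrelated noise.
#'
#' @param n_het,n_hom animals per genotype stratum (default 12 each, a
#'   24-female endpoint cohort).
#' @param r_weight planted bodyweight~bystander correlation in the het
#'   stratum (negative: more bystander editing, lower weight).
#' @param seed integer seed.
#' @return data frame with one row per animal.
#' @export
simulate_phenotype_cohort <- function(n_het = 12L, n_hom = 12L,
                                      r_weight = -0.54, seed = 1L) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  n <- n_het + n_hom
  genotype <- c(rep("het", n_het), rep("hom", n_hom))
  bys <- pmax(stats::rnorm(n, mean = 0.048, sd = 0.015), 0.001)
  desired <- pmin(pmax(stats::rnorm(n, 0.459, 0.059), 0), 1)
  indel <- pmax(stats::rnorm(n, 0.001, 0.0004), 0)

  plant_cor <- function(x, r, mu, sdev) {
    e <- stats::rnorm(length(x))
    xs <- scale(x)[, 1]
    es <- e - xs * sum(e * xs) / sum(xs^2)     # residualize: exactly orthogonal
    y <- r * xs + sqrt(1 - r^2) * scale(es)[, 1]
    mu + sdev * y
  }
  weight <- numeric(n)
  het <- genotype == "het"
  weight[het] <- plant_cor(bys[het], r_weight, 16.2, 1.2)
  weight[!het] <- plant_cor(bys[!het], -0.2, 15.3, 0.5)
  grip <- stats::rnorm(n, 1.05, 0.1)
  traverse <- pmax(stats::rnorm(n, 12, 3), 2)

  data.frame(animal_id = sprintf("F%02d", seq_len(n)),
             genotype = genotype, sex = "F", treatment = "ABEmax",
             bodyweight = weight, grip_strength = grip,
             traverse_time = traverse,
             desired_only_rate = desired,
             nonsynonymous_bystander_rate = bys,
             indel_rate = indel,
             stringsAsFactors = FALSE)
}
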