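# Independent oracles used by the test suite. These deliberately avoid the
# package's own code paths: the alignment oracle enumerates gap lengths
# explicitly instead of using affine gap states, the translation oracle goes
# through seqinr, and the classification oracle works from closed-form
# probabilities or raw read strings.

# Exhaustive DP alignment score oracle: explicit gap-length enumeration
# (O(n*m*(n+m))), same scoring contract as the package aligner — gap of
# length k costs gap_open + k*gap_extend, free leading/trailing deletions
# (read-side end gaps), N neutral.
oracle_align_score <- function(read, ref, match = 2, mismatch = -2,
                               gap_open = -10, gap_extend = -1) {
  rd <- strsplit(read, "", fixed = TRUE)[[1]]
  rf <- strsplit(ref, "", fixed = TRUE)[[1]]
  n <- length(rd); m <- length(rf)
  gapcost <- function(k) gap_open + k * gap_extend
  s <- function(a, b) if (a == "N" || b == "N") 0 else if (a == b) match else mismatch
  f <- matrix(-Inf, n + 1, m + 1)
  f[1, ] <- 0                      # free leading deletion
  for (i in 1:n) f[i + 1, 1] <- gapcost(i)
  for (i in 1:n) for (j in 1:m) {
    best <- f[i, j] + s(rd[i], rf[j])
    for (k in 1:j) best <- max(best, f[i + 1, j - k + 1] + gapcost(k))
    for (k in 1:i) best <- max(best, f[i - k + 1, j + 1] + gapcost(k))
    f[i + 1, j + 1] <- best
  }
  max(f[n + 1, ])                  # free trailing deletion
}

# Closed-form expected classification probabilities under the simulator's
# iid per-base error model (substitution-only errors, uniform over the three
# non-template bases). Works from the manifest and spec geometry only.
oracle_expected_class_probs <- function(spec, truth) {
  qa <- spec$quant_window[1]; qb <- spec$quant_window[2]
  e <- truth$error_rate
  ref_win <- strsplit(substr(spec$reference, qa + 1, qb), "", fixed = TRUE)[[1]]
  desired_win <- ref_win
  tpos <- spec$target_adenine - qa + 1
  desired_win[tpos] <- if (spec$proto_strand == "+") "G" else "C"
  idx <- build_adenine_index(spec, warn_empty = FALSE)
  g_base <- if (spec$proto_strand == "+") "G" else "C"
  nonsyn_offs <- Filter(function(off) {
    off != spec$target_adenine &&
      annotate_substitution(off, g_base, spec)$consequence %in%
        c("nonsynonymous", "stop_gained", "stop_lost")
  }, idx$ref_offset)
  syn_offs <- Filter(function(off) {
    off != spec$target_adenine &&
      annotate_substitution(off, g_base, spec)$consequence == "synonymous"
  }, idx$ref_offset)

  p_desired <- 0; p_nonsyn <- 0; p_syn <- 0; p_indel <- 0
  for (al in truth$alleles) {
    p <- al$proportion
    if (!is.null(al$indel)) { p_indel <- p_indel + p; next }
    win <- ref_win
    if (length(al$subs)) {
      offs <- as.integer(names(al$subs))
      inw <- offs >= qa & offs < qb
      win[offs[inw] - qa + 1] <- unname(al$subs)[inw]
    }
    # P(final window equals the desired-only pattern)
    agree <- ifelse(win == desired_win, 1 - e, e / 3)
    p_desired <- p_desired + p * prod(agree)
    # P(G observed at each bystander position), independent across positions
    p_g_at <- function(off) if (win[off - qa + 1] == g_base) 1 - e else e / 3
    p_any_nonsyn <- 1 - prod(1 - vapply(nonsyn_offs, p_g_at, numeric(1)))
    p_nonsyn <- p_nonsyn + p * p_any_nonsyn
    # synonymous class: >=1 synonymous bystander G and no nonsynonymous one
    p_any_syn <- 1 - prod(1 - vapply(syn_offs, p_g_at, numeric(1)))
    p_syn <- p_syn + p * p_any_syn * (1 - p_any_nonsyn)
  }
  list(desired_only = p_desired, nonsynonymous_bystander = p_nonsyn,
       synonymous_bystander = p_syn, indel = p_indel)
}

# Naive per-read string-comparison classifier for error-free, full-length
# simulations: no alignment, just direct window comparison (indel alleles
# are recognised by their length).
oracle_naive_classify <- function(seqs, spec) {
  qa <- spec$quant_window[1]; qb <- spec$quant_window[2]
  ref_len <- nchar(spec$reference)
  ref_win <- substr(spec$reference, qa + 1, qb)
  desired <- ref_win
  tpos <- spec$target_adenine - qa + 1
  substr(desired, tpos, tpos) <- if (spec$proto_strand == "+") "G" else "C"
  vapply(seqs, function(s) {
    if (nchar(s) != ref_len) return("indel")
    win <- substr(s, qa + 1, qb)
    if (win == ref_win) "wildtype"
    else if (win == desired) "desired_only"
    else "edited_other"
  }, character(1), USE.NAMES = FALSE)
}

# Random DNA of length n under the current RNG state.
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Mutate exactly k positions of a sequence (to a different base each).
mutate_k <- function(seq, k) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample(seq_along(chars), k)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}
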