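#' Off-target search parameters
#'
#' Bounded-mismatch protospacer search. The default mismatch ceiling of 6
#' matches the threshold used when re-analysing nominated sites by
#' targeted amplicon sequencing; discovery-style screens use larger
#' ceilings. Read-level pipeline parameters of the wet-lab assay
#' (mapq/start thresholds) do not apply to in-silico search and are
#' recorded as constants in `attr(, "out_of_scope")`.
#'
#' @param max_mismatches maximum Hamming distance to the protospacer.
#' @param pam_pattern IUPAC PAM pattern adjacent to the site (e.g. `NGN`
#'   for SpG, `NNNRRT` for SaKKH).
#' @param allow_gaps admit bulged sites via bounded edit distance.
#' @param gap_threshold maximum inserted/deleted bases when
#'   `allow_gaps`.
#' @param window_size nearby hits (within this many bp) are merged,
#'   keeping the lower-mismatch one.
#' @return list of class `offtarget_params`.
#' @export
offtarget_params <- function(max_mismatches = 6L, pam_pattern = "NGN",
                             allow_gaps = FALSE, gap_threshold = 3L,
                             window_size = 3L) {
  if (max_mismatches < 0) bq_stop("bequant_param_error", "max_mismatches must be >= 0")
  if (grepl(sprintf("[^%s]", paste(names(IUPAC_SETS), collapse = "")),
            toupper(pam_pattern))) {
    bq_stop("bequant_param_error", "pam_pattern '%s' is not valid IUPAC", pam_pattern)
  }
  structure(list(max_mismatches = as.integer(max_mismatches),
                 pam_pattern = toupper(pam_pattern),
                 allow_gaps = isTRUE(allow_gaps),
                 gap_threshold = as.integer(gap_threshold),
                 window_size = as.integer(window_size)),
            class = "offtarget_params",
            out_of_scope = c(mapq_threshold = 50L, start_threshold = 1L))
}

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

# one strand of one contig: vectorized sliding Hamming + PAM check
scan_strand <- function(chars, proto_chars, pam_chars, max_mm) {
  n <- length(chars); L <- length(proto_chars); P <- length(pam_chars)
  np <- n - L - P + 1L
  if (np < 1L) return(integer(0))
  mm <- rep(0L, np)
  for (k in seq_len(L)) {
    mm <- mm + (chars[(k):(k + np - 1L)] != proto_chars[k])
  }
  pam_ok <- rep(TRUE, np)
  for (k in seq_len(P)) {
    pam_ok <- pam_ok & chars[(L + k):(L + k + np - 1L)] %in% IUPAC_SETS[[pam_chars[k]]]
  }
  hits <- which(mm <= max_mm & pam_ok)
  structure(hits - 1L, mismatches = mm[hits])  # 0-based starts
}

#' Enumerate candidate off-target sites by bounded-mismatch search
#'
#' Scans both strands of every target sequence for positions whose
#' Hamming distance to the protospacer is at most `max_mismatches` and
#' whose adjacent PAM matches the IUPAC pattern. Hits within
#' `window_size` bp on one contig are merged keeping the lower-mismatch
#' hit; results are ranked by (mismatch count, contig, position). With
#' `allow_gaps`, bulged sites are additionally admitted when a bounded
#' Levenshtein alignment (at most `gap_threshold` indels, total distance
#' at most `max_mismatches`) matches ahead of a valid PAM.
#'
#' @param targets named character vector of sequences, a
#'   `Biostrings::DNAStringSet`, or a FASTA path.
#' @param protospacer protospacer sequence (5'->3', no PAM), length >= 15.
#' @param params an [offtarget_params()].
#' @return data frame of sites: `contig`, `start` (0-based), `end`,
#'   `strand`, `site` (protospacer-strand sequence), `pam`,
#'   `mismatches`, `gaps`, `rank`.
#' @export
find_candidate_sites <- function(targets, protospacer,
                                 params = offtarget_params()) {
  if (is.character(targets) && length(targets) == 1L && file.exists(targets) &&
      is.null(names(targets))) {
    targets <- Biostrings::readDNAStringSet(targets)
  }
  if (inherits(targets, "DNAStringSet")) {
    targets <- setNames(as.character(targets), names(targets))
  }
  if (length(targets) == 0L) {
    bq_stop("bequant_offtarget_error", "empty target sequence set")
  }
  if (is.null(names(targets))) names(targets) <- paste0("seq", seq_along(targets))
  protospacer <- toupper(protospacer)
  if (nchar(protospacer) < 15L) {
    bq_stop("bequant_offtarget_error", "protospacer shorter than 15 nt")
  }
  L <- nchar(protospacer)
  proto_chars <- strsplit(protospacer, "", fixed = TRUE)[[1]]
  pam_chars <- strsplit(params$pam_pattern, "", fixed = TRUE)[[1]]
  P <- length(pam_chars)

  rows <- list()
  for (ctg in names(targets)) {
    seq_fw <- toupper(targets[[ctg]])
    n <- nchar(seq_fw)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seq_fw else revcomp(seq_fw)
      chars <- strsplit(s, "", fixed = TRUE)[[1]]
      hits <- scan_strand(chars, proto_chars, pam_chars, params$max_mismatches)
      mm <- attr(hits, "mismatches")
      if (length(hits)) {
        site_seq <- substring(s, hits + 1L, hits + L)
        pam_seq <- substring(s, hits + L + 1L, hits + L + P)
        start_fw <- if (strand == "+") hits else n - hits - L
        rows[[length(rows) + 1L]] <- data.frame(
          contig = ctg, start = start_fw, end = start_fw + L,
          strand = strand, site = site_seq, pam = pam_seq,
          mismatches = as.integer(mm), gaps = 0L,
          stringsAsFactors = FALSE)
      }
      if (params$allow_gaps) {
        g <- scan_bulged(chars, proto_chars, pam_chars, params)
        if (nrow(g)) {
          g$contig <- ctg
          g$start <- if (strand == "+") g$start0 else n - g$start0 - g$len
          g$end <- g$start + g$len
          g$strand <- strand
          rows[[length(rows) + 1L]] <-
            g[, c("contig", "start", "end", "strand", "site", "pam",
                  "mismatches", "gaps")]
        }
      }
    }
  }
  sites <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(), start = integer(), end = integer(),
               strand = character(), site = character(), pam = character(),
               mismatches = integer(), gaps = integer(),
               stringsAsFactors = FALSE)
  sites <- merge_nearby_sites(sites, params$window_size)
  sites <- sites[order(sites$mismatches, sites$contig, sites$start,
                       sites$strand), , drop = FALSE]
  rownames(sites) <- NULL
  sites$rank <- seq_len(nrow(sites))
  sites
}

# bulged (gapped) candidates: anchor on PAM-valid positions, then bounded
# Levenshtein over window lengths L +- gap_threshold upstream of the PAM
# (a Hamming prefilter would be unsound: one bulge shifts every downstream
# base)
scan_bulged <- function(chars, proto_chars, pam_chars, params) {
  L <- length(proto_chars); P <- length(pam_chars)
  g <- params$gap_threshold
  n <- length(chars)
  # PAM-valid anchor positions q: PAM occupies chars[q .. q+P-1] (1-based)
  nq <- n - P + 1L
  pam_ok <- rep(TRUE, nq)
  for (k in seq_len(P)) {
    pam_ok <- pam_ok & chars[(k):(k + nq - 1L)] %in% IUPAC_SETS[[pam_chars[k]]]
  }
  anchors <- which(pam_ok)
  anchors <- anchors[anchors > L - g]           # room for a window upstream
  out <- list()
  proto <- paste(proto_chars, collapse = "")
  for (q in anchors) {
    best <- NULL
    for (len in max(1L, L - g):(L + g)) {
      if (q - len < 1L) next
      win <- paste(chars[(q - len):(q - 1L)], collapse = "")
      d <- utils::adist(proto, win, counts = TRUE)
      cnt <- attr(d, "counts")[1, 1, ]
      gaps <- cnt["ins"] + cnt["del"]
      if (gaps >= 1L && gaps <= g && d[1, 1] <= params$max_mismatches &&
          (is.null(best) || d[1, 1] < best$dist)) {
        best <- list(dist = d[1, 1], len = len, gaps = as.integer(gaps),
                     site = win,
                     pam = paste(chars[q:(q + P - 1L)], collapse = ""))
      }
    }
    if (!is.null(best)) {
      out[[length(out) + 1L]] <- data.frame(
        start0 = q - best$len - 1L, len = best$len, site = best$site,
        pam = best$pam, mismatches = as.integer(best$dist),
        gaps = best$gaps, stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(start0 = integer(), len = integer(), site = character(),
               pam = character(), mismatches = integer(), gaps = integer(),
               stringsAsFactors = FALSE)
}

# merge hits within window_size bp on one contig, keeping the
# lower-mismatch (then leftmost, then '+' strand) representative
merge_nearby_sites <- function(sites, window_size) {
  if (nrow(sites) < 2L) return(sites)
  keep <- logical(0)
  out <- list()
  for (ctg in unique(sites$contig)) {
    s <- sites[sites$contig == ctg, , drop = FALSE]
    s <- s[order(s$start, s$strand), , drop = FALSE]
    cluster <- cumsum(c(1L, diff(s$start) > window_size))
    for (cl in unique(cluster)) {
      grp <- s[cluster == cl, , drop = FALSE]
      grp <- grp[order(grp$mismatches, grp$start, grp$strand), , drop = FALSE]
      out[[length(out) + 1L]] <- grp[1L, , drop = FALSE]
    }
  }
  do.call(rbind, out)
}

#' Top-ranked off-target sites
#'
#' @param sites result of [find_candidate_sites()].
#' @param n how many (fewer returned if fewer exist).
#' @return the first `n` sites by rank.
#' @export
top_n_sites <- function(sites, n = 5L) {
  sites[order(sites$rank), , drop = FALSE][seq_len(min(n, nrow(sites))), ,
                                           drop = FALSE]
}

#' Write sites as a BED-like TSV
#'
#' Columns: contig, start, end, strand, mismatches, gaps, site, pam, rank.
#'
#' @param sites result of [find_candidate_sites()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  write.table(sites[, c("contig", "start", "end", "strand", "mismatches",
                        "gaps", "site", "pam", "rank")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Derive an amplicon spec for quantifying editing at an off-target site
#'
#' Builds an [amplicon_spec()] around a nominated site so the standard
#' quantification stack can be run on reads from a targeted amplicon over
#' that site. The target adenine defaults to the adenine at the same
#' protospacer position as the on-target spec's target (falling back to
#' the first adenine of the site). No CDS is attached: consequence calls
#' are not made at (typically intergenic or intronic) off-target sites.
#'
#' @param targets the sequence set passed to [find_candidate_sites()].
#' @param site one row of the sites data frame.
#' @param on_spec the on-target [amplicon_spec()] (for the target
#'   protospacer position).
#' @param flank flanking bases on each side of the site.
#' @return an `amplicon_spec`.
#' @export
off_target_amplicon_spec <- function(targets, site, on_spec, flank = 60L) {
  if (inherits(targets, "DNAStringSet")) {
    targets <- setNames(as.character(targets), names(targets))
  }
  seq_fw <- toupper(targets[[site$contig]])
  lo <- max(0L, site$start - flank)
  hi <- min(nchar(seq_fw), site$end + flank)
  reference <- substr(seq_fw, lo + 1L, hi)
  start_local <- site$start - lo
  L <- site$end - site$start

  # protospacer-strand positions of adenines within the site
  site_chars <- strsplit(site$site, "", fixed = TRUE)[[1]]
  a_pos <- which(site_chars == "A")
  if (!length(a_pos)) {
    bq_stop("bequant_offtarget_error",
            "site at %s:%d has no adenine to quantify", site$contig, site$start)
  }
  ps <- on_spec$protospacers
  on_target_pos <- if (on_spec$proto_strand == "+") {
    on_spec$target_adenine - ps$start[1] + 1L
  } else {
    ps$start[1] + nchar(ps$seq[1]) - on_spec$target_adenine
  }
  tgt_pos <- if (on_target_pos %in% a_pos) on_target_pos else a_pos[1]
  target_offset <- if (site$strand == "+") {
    start_local + tgt_pos - 1L
  } else {
    start_local + L - tgt_pos
  }
  amplicon_spec(
    locus_name = sprintf("offtarget_%s_%d", site$contig, site$start),
    reference = reference,
    protospacers = data.frame(label = "offtarget_site", seq = site$site,
                              start = start_local, strand = site$strand,
                              pam = site$pam, stringsAsFactors = FALSE),
    target_adenine = target_offset)
}
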