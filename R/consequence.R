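#' Codon number and within-codon position of a CDS coordinate
#'
#' HGVS-style: c. position 1 is the A of the start codon; codon `k` spans
#' c. positions `3k-2 .. 3k`.
#'
#' @param cds_pos 1-based coding position(s).
#' @return data frame with `codon_number` and `position_in_codon` (1-3).
#' @export
#' @examples
#' codon_index(728)  # codon 243, position 2
codon_index <- function(cds_pos) {
  cds_pos <- as.integer(cds_pos)
  if (any(cds_pos < 1L)) {
    bq_stop("bequant_domain_error", "cds_pos must be >= 1")
  }
  data.frame(codon_number = as.integer(ceiling(cds_pos / 3)),
             position_in_codon = ((cds_pos - 1L) %% 3L) + 1L)
}

#' Translate a codon under the standard genetic code
#' @param codon character vector of triplets.
#' @return single-letter amino acids (`*` for stop).
#' @export
translate_codon <- function(codon) {
  codon <- toupper(codon)
  aa <- Biostrings::GENETIC_CODE[codon]
  if (anyNA(aa)) {
    bq_stop("bequant_domain_error", "invalid codon: %s", codon[which(is.na(aa))[1]])
  }
  unname(aa)
}

#' Classify a coding substitution as synonymous or nonsynonymous
#'
#' Substitutes `alt` at coding position `cds_pos` of `cds_seq` (both on
#' the coding strand, `cds_seq` starting at c. position `c_start`) and
#' compares the translated codons. Stop transitions are labelled
#' distinctly.
#'
#' @param cds_seq coding-strand DNA of the (local) CDS segment.
#' @param cds_pos 1-based c. position of the substituted base.
#' @param alt alternate base on the coding strand.
#' @param c_start c. position of the first base of `cds_seq` (default 1,
#'   i.e. `cds_seq` starts at the start codon).
#' @return list with `codon_number`, `position_in_codon`, `ref_codon`,
#'   `alt_codon`, `ref_aa`, `alt_aa` and
#'   `consequence` in `{synonymous, nonsynonymous, stop_gained, stop_lost}`.
#' @export
#' @examples
#' classify_substitution("CCG", 2, "T", c_start = 1)  # Pro -> Leu
classify_substitution <- function(cds_seq, cds_pos, alt, c_start = 1L) {
  cds_seq <- toupper(cds_seq)
  alt <- toupper(alt)
  idx <- cds_pos - c_start + 1L
  if (idx < 1L || idx > nchar(cds_seq)) {
    bq_stop("bequant_domain_error",
            "cds_pos %d outside the provided CDS segment", cds_pos)
  }
  ref_base <- substr(cds_seq, idx, idx)
  if (identical(ref_base, alt)) {
    bq_stop("bequant_domain_error",
            "alt base '%s' equals the reference base at c.%d (not a substitution)",
            alt, cds_pos)
  }
  ci <- codon_index(cds_pos)
  codon_start_c <- (ci$codon_number - 1L) * 3L + 1L
  codon_idx <- codon_start_c - c_start + 1L
  if (codon_idx < 1L || codon_idx + 2L > nchar(cds_seq)) {
    bq_stop("bequant_domain_error",
            "codon %d not fully contained in the provided CDS segment", ci$codon_number)
  }
  ref_codon <- substr(cds_seq, codon_idx, codon_idx + 2L)
  alt_codon <- ref_codon
  substr(alt_codon, ci$position_in_codon, ci$position_in_codon) <- alt
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  consequence <- if (ref_aa == alt_aa) "synonymous"
  else if (alt_aa == "*") "stop_gained"
  else if (ref_aa == "*") "stop_lost"
  else "nonsynonymous"
  list(codon_number = ci$codon_number,
       position_in_codon = ci$position_in_codon,
       ref_codon = ref_codon, alt_codon = alt_codon,
       ref_aa = ref_aa, alt_aa = alt_aa, consequence = consequence)
}

#' Annotate a single reference-strand substitution against a locus
#'
#' Maps a 0-based reference offset to its c. position via the spec's CDS
#' anchor (respecting the coding strand: on the minus strand the alt base
#' is complemented before codon substitution) and classifies it.
#' Substitutions mapping outside the supplied CDS segment are classified
#' `noncoding` with a warning.
#'
#' @param ref_offset 0-based reference offset.
#' @param alt alternate base on the reference plus strand.
#' @param spec an [amplicon_spec()] with a `cds` component.
#' @return list with `ref_offset`, `cds_position` and, for coding
#'   positions, the fields of [classify_substitution()].
#' @export
annotate_substitution <- function(ref_offset, alt, spec) {
  cds <- spec$cds
  if (is.null(cds)) {
    return(list(ref_offset = ref_offset, cds_position = NA_integer_,
                consequence = "noncoding"))
  }
  cpos <- if (cds$strand == "+") {
    cds$anchor_cpos + (ref_offset - cds$anchor_offset)
  } else {
    cds$anchor_cpos - (ref_offset - cds$anchor_offset)
  }
  idx <- cpos - cds$c_start + 1L
  codon_n <- ceiling(cpos / 3)
  codon_lo <- (codon_n - 1L) * 3L + 1L - cds$c_start + 1L
  if (idx < 1L || idx > nchar(cds$seq) ||
      codon_lo < 1L || codon_lo + 2L > nchar(cds$seq)) {
    warning(sprintf("substitution at offset %d maps outside the provided CDS segment; classified noncoding",
                    ref_offset), call. = FALSE)
    return(list(ref_offset = ref_offset, cds_position = as.integer(cpos),
                consequence = "noncoding"))
  }
  alt_coding <- if (cds$strand == "+") alt else comp_base(alt)
  out <- classify_substitution(cds$seq, cpos, alt_coding, c_start = cds$c_start)
  c(list(ref_offset = ref_offset, cds_position = as.integer(cpos)), out)
}

#' Annotate an allele's substitution set and assign its outcome class
#'
#' Bystanders are A-to-G conversions (on the protospacer strand) at
#' non-target adenines of the combined protospacer interval. Class
#' precedence is total: any nonsynonymous (or stop) bystander makes the
#' allele `nonsynonymous_bystander`; otherwise any bystander makes it
#' `synonymous_bystander`; an allele whose only substitution is the
#' target A-to-G is `on_target_only`; no substitutions is `wildtype`;
#' anything else (non-A-to-G substitutions only, e.g. sequencing errors)
#' is `other`.
#'
#' @param subs data frame with columns `ref_offset` (0-based) and `alt`
#'   (reference plus-strand base), or an empty data frame.
#' @param spec an [amplicon_spec()].
#' @param index optional pre-built [build_adenine_index()].
#' @return list with `class` and `calls` (one annotation per bystander).
#' @export
annotate_allele <- function(subs, spec, index = NULL) {
  if (is.null(index)) index <- build_adenine_index(spec, warn_empty = FALSE)
  if (is.null(subs) || nrow(subs) == 0L) {
    return(list(class = "wildtype", calls = list()))
  }
  edited_alt <- if (spec$proto_strand == "+") "G" else "C"
  edited_ref <- if (spec$proto_strand == "+") "A" else "T"
  ref_bases <- substring(spec$reference, subs$ref_offset + 1L, subs$ref_offset + 1L)
  is_ag <- ref_bases == edited_ref & subs$alt == edited_alt &
    subs$ref_offset %in% index$ref_offset
  is_target <- subs$ref_offset == spec$target_adenine & is_ag
  is_bystander <- is_ag & !is_target

  calls <- lapply(which(is_bystander), function(i) {
    call <- annotate_substitution(subs$ref_offset[i], subs$alt[i], spec)
    call$A_label <- index$label[match(subs$ref_offset[i], index$ref_offset)]
    call
  })
  cons <- vapply(calls, function(x) x$consequence, character(1))
  cls <- if (any(cons %in% c("nonsynonymous", "stop_gained", "stop_lost"))) {
    "nonsynonymous_bystander"
  } else if (any(cons == "synonymous")) {
    "synonymous_bystander"
  } else if (length(calls) > 0L) {
    # bystander A->G outside the supplied CDS (e.g. intronic off-target
    # sites): no consequence call possible, grouped with 'other'
    "other"
  } else if (any(is_target) && all(is_target)) {
    "on_target_only"
  } else {
    "other"
  }
  list(class = cls, calls = calls)
}
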