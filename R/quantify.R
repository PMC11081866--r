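#' Number the adenines of the combined protospacer interval
#'
#' Adenines are labelled `A1 ... Ak` by their 5'->3' position on the
#' protospacer strand, over the union of all protospacer intervals at the
#' locus (so the numbering is shared across editor variants whose guides
#' overlap).
#'
#' @param spec an [amplicon_spec()].
#' @param warn_empty warn when the interval holds no adenines.
#' @return data frame with `label`, `ref_offset` (0-based) and
#'   `proto_pos` (1-based position within the union interval, 5'->3' on
#'   the protospacer strand).
#' @export
#' @examples
#' build_adenine_index(example_amplicon_spec())
build_adenine_index <- function(spec, warn_empty = TRUE) {
  ps <- spec$protospacers
  if (length(unique(ps$strand)) > 1L) {
    bq_stop("bequant_config_error",
            "protospacers on opposite strands at one locus are unsupported")
  }
  strand <- ps$strand[1]
  lo <- min(ps$start)
  hi <- max(ps$start + nchar(ps$seq))
  offs <- lo:(hi - 1L)
  bases <- strsplit(substr(spec$reference, lo + 1L, hi), "", fixed = TRUE)[[1]]
  if (strand == "-") {
    offs <- rev(offs)
    bases <- comp_base(rev(bases))
  }
  is_a <- bases == "A"
  idx <- data.frame(label = if (any(is_a)) paste0("A", seq_len(sum(is_a))) else character(0),
                    ref_offset = offs[is_a],
                    proto_pos = which(is_a),
                    stringsAsFactors = FALSE)
  if (nrow(idx) == 0L && warn_empty) {
    warning(sprintf("locus '%s': no adenines in the combined protospacer interval",
                    spec$locus_name), call. = FALSE)
  }
  idx
}

# Split a window allele string into its per-reference-slot characters and
# insertion flags. Lowercase runs are insertions sitting before the next
# reference slot.
window_profile <- function(allele) {
  chars <- strsplit(allele, "", fixed = TRUE)[[1]]
  is_ins <- chars %in% c("a", "c", "g", "t")
  slots <- chars[!is_ins]
  width <- length(slots)
  ins_before <- logical(width + 1L)
  slot_i <- cumsum(!is_ins)          # slot index each char belongs to / precedes
  if (any(is_ins)) {
    ins_before[pmin(slot_i[is_ins] + 1L, width + 1L)] <- TRUE
  }
  list(slots = slots, ins_before = ins_before)
}

# Substitution set of a window allele string relative to the reference.
window_substitutions <- function(allele, spec) {
  qa <- spec$quant_window[1]
  prof <- window_profile(allele)
  ref_chars <- strsplit(substr(spec$reference, qa + 1L, spec$quant_window[2]),
                        "", fixed = TRUE)[[1]]
  if (length(prof$slots) != length(ref_chars)) {
    bq_stop("bequant_quant_error", "window allele string has wrong width")
  }
  sub_i <- which(prof$slots != ref_chars & prof$slots %in% c("A", "C", "G", "T"))
  data.frame(ref_offset = qa + sub_i - 1L,
             ref = ref_chars[sub_i], alt = prof$slots[sub_i],
             stringsAsFactors = FALSE)
}

#' Build the allele table from aligned reads
#'
#' Accepted reads are grouped by their gapped sequence over the
#' quantification window together with the indel-window flag; each unique
#' combination becomes one allele row with its count, frequency,
#' substitution annotation (`A_x` notation for protospacer-strand A-to-G
#' calls, `offset:REF>ALT` otherwise) and outcome class.
#'
#' Classes are mutually exclusive, with indel membership dominating: an
#' allele with an indel in the indel window is reported as `indel`
#' regardless of substitutions; the rest follow [annotate_allele()]
#' precedence (nonsynonymous_bystander > synonymous_bystander >
#' on_target_only > wildtype, `other` for remaining substitution
#' patterns).
#'
#' @param alignments data frame from [align_reads()].
#' @param spec an [amplicon_spec()].
#' @return data frame of class `allele_table`, ordered by decreasing
#'   count, with attributes `n_aligned`, `spec`, `adenine_index`.
#' @export
build_allele_table <- function(alignments, spec) {
  acc <- alignments[alignments$accepted, , drop = FALSE]
  if (nrow(acc) == 0L) {
    bq_stop("bequant_quant_error", "no accepted alignments to quantify")
  }
  idx <- build_adenine_index(spec, warn_empty = FALSE)
  key <- paste0(acc$window, "|", as.integer(acc$indel_in_window))
  tab <- table(key)
  keys <- names(tab)
  counts <- as.integer(tab)
  windows <- sub("\\|[01]$", "", keys)
  indel_flag <- endsWith(keys, "|1")
  n_aligned <- nrow(acc)

  cls <- character(length(keys))
  subs_str <- character(length(keys))
  has_gap <- grepl("[-acgt]", windows)
  for (i in seq_along(keys)) {
    subs <- window_substitutions(windows[i], spec)
    ann <- annotate_allele(subs, spec, index = idx)
    cls[i] <- if (indel_flag[i] || has_gap[i]) "indel" else ann$class
    if (nrow(subs)) {
      lab <- character(nrow(subs))
      for (j in seq_len(nrow(subs))) {
        m <- match(subs$ref_offset[j], idx$ref_offset)
        edited_ref <- if (spec$proto_strand == "+") "A" else "T"
        edited_alt <- if (spec$proto_strand == "+") "G" else "C"
        lab[j] <- if (!is.na(m) && subs$ref[j] == edited_ref &&
                      subs$alt[j] == edited_alt) {
          paste0(idx$label[m], ">G")
        } else {
          sprintf("%d:%s>%s", subs$ref_offset[j], subs$ref[j], subs$alt[j])
        }
      }
      subs_str[i] <- paste(lab, collapse = ";")
    }
  }
  out <- data.frame(allele = windows, count = counts,
                    frequency = counts / n_aligned,
                    substitutions = subs_str,
                    has_indel_in_window = indel_flag | has_gap,
                    class = cls, stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$allele), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_aligned") <- n_aligned
  attr(out, "spec") <- spec
  attr(out, "adenine_index") <- idx
  class(out) <- c("allele_table", "data.frame")
  out
}

#' Desired-edit-only efficiency
#'
#' Fraction of aligned reads whose only deviation from the reference
#' within the quantification window is the target A-to-G, with no indel
#' in the indel window: (reads containing only the desired edit) /
#' (total aligned reads).
#'
#' @param table an [build_allele_table()] result.
#' @param spec the matching [amplicon_spec()] (defaults to the table's).
#' @return a fraction in `[0, 1]`.
#' @export
desired_only_rate <- function(table, spec = attr(table, "spec")) {
  n_aligned <- attr(table, "n_aligned")
  qa <- spec$quant_window[1]
  ref_win <- substr(spec$reference, qa + 1L, spec$quant_window[2])
  desired <- ref_win
  pos <- spec$target_adenine - qa + 1L
  substr(desired, pos, pos) <- if (spec$proto_strand == "+") "G" else "C"
  hit <- table$allele == desired & !table$has_indel_in_window
  sum(table$count[hit]) / n_aligned
}

#' Per-adenine A-to-G editing rates
#'
#' For each labelled adenine, the fraction of aligned reads carrying a G
#' (on the protospacer strand) at that position. Reads with an indel
#' overlapping the position, or an N call there, are excluded from that
#' position's numerator and denominator.
#'
#' @param table an [build_allele_table()] result.
#' @param index an adenine index (defaults to the table's).
#' @return named numeric vector, one rate per `A_x` label (`NA` when no
#'   read covers the position).
#' @export
per_adenine_rates <- function(table, index = attr(table, "adenine_index")) {
  spec <- attr(table, "spec")
  qa <- spec$quant_window[1]; qb <- spec$quant_window[2]
  edited <- if (spec$proto_strand == "+") "G" else "C"
  rates <- setNames(rep(NA_real_, nrow(index)), index$label)
  if (nrow(index) == 0L || nrow(table) == 0L) return(rates)
  profs <- lapply(table$allele, window_profile)
  for (k in seq_len(nrow(index))) {
    off <- index$ref_offset[k]
    if (off < qa || off >= qb) next
    slot <- off - qa + 1L
    excl <- vapply(profs, function(p) {
      p$slots[slot] %in% c("-", "N") || p$ins_before[slot] || p$ins_before[slot + 1L]
    }, logical(1))
    carrier <- !excl & vapply(profs, function(p) p$slots[slot] == edited, logical(1))
    denom <- sum(table$count[!excl])
    rates[k] <- if (denom > 0) sum(table$count[carrier]) / denom else NA_real_
  }
  rates
}

#' Windowed indel rate
#'
#' Fraction of aligned reads with at least one inserted or deleted base
#' whose left-aligned placement overlaps the indel window (the window
#' covering both the deamination positions and the nick site):
#' (indel-containing reads) / (total aligned reads).
#'
#' @param x either the data frame from [align_reads()] or an
#'   [build_allele_table()] result.
#' @param spec the matching [amplicon_spec()] (unused for allele tables;
#'   kept for a uniform signature).
#' @return a fraction in `[0, 1]`.
#' @export
indel_rate <- function(x, spec = NULL) {
  if (inherits(x, "allele_table")) {
    return(sum(x$count[x$has_indel_in_window]) / attr(x, "n_aligned"))
  }
  acc <- x[x$accepted, , drop = FALSE]
  if (nrow(acc) == 0L) return(NA_real_)
  mean(acc$indel_in_window)
}

#' Filter an allele table for display
#'
#' Removes rows below a display frequency from the *rendered* report.
#' Summary statistics always use the unfiltered table; the default
#' threshold hides outcomes with a frequency below 0.20%.
#'
#' @param table an allele table.
#' @param min_freq minimum displayed frequency (default 0.002).
#' @return the filtered table (attributes preserved).
#' @export
filter_alleles_for_report <- function(table, min_freq = 0.002) {
  keep <- table$frequency >= min_freq
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("n_aligned", "spec", "adenine_index")] <-
    attributes(table)[c("n_aligned", "spec", "adenine_index")]
  class(out) <- class(table)
  out
}

#' Per-sample editing summary
#'
#' Combines the allele table into the per-sample rates: desired-edit-only
#' efficiency, per-adenine A-to-G rates, synonymous and nonsynonymous
#' bystander rates (fractions of aligned reads in the respective mutually
#' exclusive outcome class; indel reads are counted once, as indels), and
#' the windowed indel rate.
#'
#' @param table an [build_allele_table()] result.
#' @param sample_id sample label carried into the output.
#' @return object of class `editing_summary`.
#' @export
summarize_editing <- function(table, sample_id = "sample") {
  spec <- attr(table, "spec")
  n_aligned <- attr(table, "n_aligned")
  class_counts <- tapply(table$count, table$class, sum)
  cc <- function(cl) if (cl %in% names(class_counts)) unname(class_counts[cl]) else 0L
  out <- list(sample_id = sample_id,
              locus = spec$locus_name,
              n_aligned = n_aligned,
              desired_only_rate = desired_only_rate(table, spec),
              per_adenine_rate = per_adenine_rates(table),
              synonymous_bystander_rate = cc("synonymous_bystander") / n_aligned,
              nonsynonymous_bystander_rate = cc("nonsynonymous_bystander") / n_aligned,
              indel_rate = indel_rate(table),
              class_counts = class_counts)
  class(out) <- "editing_summary"
  out
}

#' @export
print.editing_summary <- function(x, ...) {
  cat(sprintf("editing summary for '%s' at %s (%d aligned reads)\n",
              x$sample_id, x$locus, x$n_aligned))
  cat(sprintf("  desired-edit-only: %.2f%%\n", 100 * x$desired_only_rate))
  cat(sprintf("  bystanders: %.2f%% synonymous, %.2f%% nonsynonymous\n",
              100 * x$synonymous_bystander_rate,
              100 * x$nonsynonymous_bystander_rate))
  cat(sprintf("  indels in window: %.2f%%\n", 100 * x$indel_rate))
  pa <- paste(sprintf("%s=%.2f%%", names(x$per_adenine_rate),
                      100 * x$per_adenine_rate), collapse = ", ")
  cat("  per-adenine:", pa, "\n")
  invisible(x)
}

#' One-row data frame form of an editing summary
#' @param x an `editing_summary`.
#' @param ... unused.
#' @return data frame with one row.
#' @method as.data.frame editing_summary
#' @export
as.data.frame.editing_summary <- function(x, ...) {
  base <- data.frame(sample_id = x$sample_id, locus = x$locus,
                     n_aligned = x$n_aligned,
                     desired_only_rate = x$desired_only_rate,
                     synonymous_bystander_rate = x$synonymous_bystander_rate,
                     nonsynonymous_bystander_rate = x$nonsynonymous_bystander_rate,
                     indel_rate = x$indel_rate,
                     stringsAsFactors = FALSE)
  pa <- as.data.frame(as.list(setNames(x$per_adenine_rate,
                                       paste0("rate_", names(x$per_adenine_rate)))))
  if (ncol(pa)) cbind(base, pa) else base
}
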