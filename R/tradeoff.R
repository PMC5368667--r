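#' Significance stars
#'
#' `*` for p < 0.05 and `**` for p < 0.01, both strict; empty otherwise.
#' `NA` p-values (not-computable comparisons) yield the dagger marker.
#'
#' @param p P-value.
#' @return `""`, `"*"`, `"**"` or `"†"`.
#' @export
significance_stars <- function(p) {
  if (is.na(p)) return("†")
  if (p < 0.01) return("**")
  if (p < 0.05) return("*")
  ""
}

#' Two-sample Student's t-test
#'
#' Two-tailed two-sample t-test on replicate values, equal-variance by
#' default (classical Student's test, df = n_a + n_b - 2) with Welch
#' available. Replicate pairs with n = 2 per group (df = 2) are tested
#' like any other. A sample with fewer than 2 values yields a
#' not-computable result (`NA` statistics) rather than an error; two
#' zero-variance samples are handled directly (p = 1 for equal means,
#' p = 0 otherwise) since the t statistic degenerates.
#'
#' @param sample_a,sample_b Numeric replicate vectors.
#' @param variant `"equal"` (pooled variance) or `"welch"`.
#' @return List (`t_test_result`): `t_statistic`, `df`, `p_two_tailed`,
#'   `stars`, `variant`.
#' @export
students_t_test <- function(sample_a, sample_b,
                            variant = c("equal", "welch")) {
  variant <- match.arg(variant)
  res <- list(t_statistic = NA_real_, df = NA_real_,
              p_two_tailed = NA_real_, stars = "†", variant = variant)
  if (length(sample_a) < 2L || length(sample_b) < 2L) {
    return(structure(res, class = "t_test_result"))
  }
  if (stats::sd(sample_a) == 0 && stats::sd(sample_b) == 0) {
    same <- mean(sample_a) == mean(sample_b)
    res$t_statistic <- if (same) 0 else Inf * sign(mean(sample_a) - mean(sample_b))
    res$df <- length(sample_a) + length(sample_b) - 2
    res$p_two_tailed <- if (same) 1 else 0
  } else {
    tt <- stats::t.test(sample_a, sample_b,
                        var.equal = (variant == "equal"),
                        alternative = "two.sided")
    res$t_statistic <- unname(tt$statistic)
    res$df <- unname(tt$parameter)
    res$p_two_tailed <- tt$p.value
  }
  res$stars <- significance_stars(res$p_two_tailed)
  structure(res, class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("<t-test (%s): t = %.3g, df = %.3g, p = %.3g %s>\n",
              x$variant, x$t_statistic, x$df, x$p_two_tailed, x$stars))
  invisible(x)
}

classify_axis <- function(delta, p, pos_label, neg_label) {
  if (is.na(delta)) return("not-computable")
  if (is.na(p)) {
    # unmeasurable reversion under a measurable context: the sign of the
    # qualitative change still classifies the mutation
    return(if (delta > 0) pos_label else neg_label)
  }
  if (p >= 0.05) return("neutral")
  if (delta > 0) pos_label else neg_label
}

#' Effect of one mutation from a context/reversion comparison
#'
#' Compares a context variant (the variant that acquired the mutation)
#' against the construct with that single mutation reverted to wild type.
#' Deltas are context minus reverted, so a positive affinity delta means
#' the mutation enhances binding and a positive stability delta means it
#' stabilizes. P-values come from [students_t_test()] on the
#' replicate-level values carried by the summaries.
#'
#' Classification: `neutral` when p >= 0.05; otherwise the delta's sign
#' picks enhancing/reducing (affinity) or stabilizing/destabilizing
#' (stability). When the reversion construct's affinity is unmeasurable
#' but the context's is not, the p-value is not-computable (dagger) yet
#' the mutation is classified from the qualitative loss of binding; when
#' the context itself is unmeasurable the class is `not-computable`.
#'
#' @param context_summary `affinity_summary` or `tm_estimate` for the
#'   context variant.
#' @param reverted_summary Same kind of summary for the single-reversion
#'   construct.
#' @param mutation The forward mutation being assessed (`vh_mutation` or
#'   string).
#' @param context Context variant label (defaults to the summary's).
#' @param test_variant Passed to [students_t_test()].
#' @return One-row data frame with the filled axis (`delta_*`, `sd_*`,
#'   `p_*`, `*_class`).
#' @export
reversion_effect <- function(context_summary, reverted_summary, mutation,
                             context = NULL, test_variant = "equal") {
  mutation <- as_mutation(mutation)
  is_aff <- inherits(context_summary, "affinity_summary")
  if (is_aff != inherits(reverted_summary, "affinity_summary")) {
    stop("context and reverted summaries are of different kinds")
  }
  if (is.null(context)) context <- context_summary$variant

  rec <- data.frame(mutation = format(mutation),
                    position = format(mutation$position),
                    context_variant = context,
                    stringsAsFactors = FALSE)
  if (is_aff) {
    if (!context_summary$measurable) {
      rec$delta_ka <- NA_real_; rec$sd_ka <- NA_real_; rec$p_ka <- NA_real_
      rec$affinity_class <- "not-computable"
      rec$affinity_stars <- "†"
    } else if (!reverted_summary$measurable) {
      rec$delta_ka <- context_summary$mean_ka # binding lost on reversion
      rec$sd_ka <- context_summary$sd_ka
      rec$p_ka <- NA_real_
      rec$affinity_class <- classify_axis(rec$delta_ka, NA_real_,
                                          "enhancing", "reducing")
      rec$affinity_stars <- "†"
    } else {
      tt <- students_t_test(context_summary$values, reverted_summary$values,
                            test_variant)
      rec$delta_ka <- context_summary$mean_ka - reverted_summary$mean_ka
      rec$sd_ka <- sqrt(context_summary$sd_ka^2 + reverted_summary$sd_ka^2)
      rec$p_ka <- tt$p_two_tailed
      rec$affinity_class <- classify_axis(rec$delta_ka, rec$p_ka,
                                          "enhancing", "reducing")
      rec$affinity_stars <- tt$stars
    }
  } else {
    tt <- students_t_test(context_summary$values, reverted_summary$values,
                          test_variant)
    rec$delta_tm <- context_summary$tm_app - reverted_summary$tm_app
    rec$sd_tm <- sqrt(context_summary$sd^2 + reverted_summary$sd^2)
    rec$p_tm <- tt$p_two_tailed
    rec$stability_class <- classify_axis(rec$delta_tm, rec$p_tm,
                                         "stabilizing", "destabilizing")
    rec$stability_stars <- tt$stars
  }
  rec
}

# Identify (context, reversion construct, forward mutation) triples in a
# lineage: a reversion construct carries exactly one mutation from its
# parent, and that mutation undoes one the parent accumulated.
reversion_pairs <- function(lineage) {
  acc <- list() # accumulated forward mutations per variant
  for (v in lineage) {
    acc[[v$name]] <- if (is.null(v$parent)) character(0) else {
      c(acc[[v$parent]], v$mutations_from_parent)
    }
  }
  out <- list()
  for (v in lineage) {
    if (is.null(v$parent) || length(v$mutations_from_parent) != 1L) next
    rev_str <- format(reverse_mutation(v$mutations_from_parent))
    if (rev_str %in% acc[[v$parent]]) {
      out[[length(out) + 1L]] <- list(context = v$parent,
                                      construct = v$name,
                                      mutation = rev_str)
    }
  }
  out
}

#' Assemble the per-mutation affinity/stability trade-off table
#'
#' For every single-reversion construct in the lineage, pairs it with its
#' context variant and fills both axes of the trade-off record: delta K_A
#' and delta Tm (context minus reverted, with propagated SDs), replicate
#' t-test p-values, significance stars and the
#' enhancing/neutral/reducing x stabilizing/neutral/destabilizing
#' classification. This is the quadrant table underlying the
#' reversion-scan figures.
#'
#' @param affinity Named list of `affinity_summary`s (constructs and
#'   contexts), e.g. from [fit_all_titrations()].
#' @param stability Named list of summarized `tm_estimate`s, e.g. from
#'   [fit_all_melts()].
#' @param lineage Named list of `vh_variant`s containing the context
#'   variants and the single-reversion constructs.
#' @param test_variant Passed to [students_t_test()].
#' @return Data frame, one row per (mutation, context), ordered by Kabat
#'   position.
#' @export
build_tradeoff_table <- function(affinity, stability, lineage,
                                 test_variant = "equal") {
  pairs <- reversion_pairs(lineage)
  # only pairs with at least one kind of summary yield a record
  pairs <- Filter(function(p) {
    (!is.null(affinity[[p$context]]) && !is.null(affinity[[p$construct]])) ||
      (!is.null(stability[[p$context]]) && !is.null(stability[[p$construct]]))
  }, pairs)
  if (length(pairs) == 0L) stop("no single-reversion constructs in lineage")
  rows <- lapply(pairs, function(p) {
    rec <- data.frame(mutation = p$mutation,
                      position = format(as_mutation(p$mutation)$position),
                      context_variant = p$context,
                      stringsAsFactors = FALSE)
    if (!is.null(affinity[[p$context]]) && !is.null(affinity[[p$construct]])) {
      a <- reversion_effect(affinity[[p$context]], affinity[[p$construct]],
                            p$mutation, context = p$context,
                            test_variant = test_variant)
      rec <- cbind(rec, a[, c("delta_ka", "sd_ka", "p_ka",
                              "affinity_class", "affinity_stars")])
    }
    if (!is.null(stability[[p$context]]) && !is.null(stability[[p$construct]])) {
      s <- reversion_effect(stability[[p$context]], stability[[p$construct]],
                            p$mutation, context = p$context,
                            test_variant = test_variant)
      rec <- cbind(rec, s[, c("delta_tm", "sd_tm", "p_tm",
                              "stability_class", "stability_stars")])
    }
    rec
  })
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (cl in setdiff(cols, names(r))) r[[cl]] <- NA
    r[, cols]
  })
  out <- do.call(rbind, rows)
  dup <- duplicated(out[, c("mutation", "context_variant")])
  if (any(dup)) stop("duplicate summaries for one reversion construct")
  out[kabat_order(out$position), , drop = FALSE]
}

#' Compare two variants directly
#'
#' Replicate-level comparison of two summaries of the same kind (e.g. the
#' evolved variant versus a multi-mutation scaffold construct): delta,
#' propagated SD, and a two-sample t-test.
#'
#' @param summary_a,summary_b Two `affinity_summary`s or two
#'   `tm_estimate`s.
#' @param test_variant Passed to [students_t_test()].
#' @return One-row data frame (`delta`, `sd`, `p`, `stars`).
#' @export
compare_variants <- function(summary_a, summary_b, test_variant = "equal") {
  is_aff <- inherits(summary_a, "affinity_summary")
  if (is_aff != inherits(summary_b, "affinity_summary")) {
    stop("summaries are of different kinds")
  }
  va <- if (is_aff) summary_a$values else summary_a$values
  vb <- if (is_aff) summary_b$values else summary_b$values
  ma <- if (is_aff) summary_a$mean_ka else summary_a$tm_app
  mb <- if (is_aff) summary_b$mean_ka else summary_b$tm_app
  sa <- if (is_aff) summary_a$sd_ka else summary_a$sd
  sb <- if (is_aff) summary_b$sd_ka else summary_b$sd
  tt <- students_t_test(va, vb, test_variant)
  data.frame(a = summary_a$variant, b = summary_b$variant,
             delta = ma - mb, sd = sqrt(sa^2 + sb^2),
             p = tt$p_two_tailed, stars = tt$stars,
             stringsAsFactors = FALSE)
}

#' Write a trade-off table as CSV plus a JSON twin
#'
#' @param table Data frame from [build_tradeoff_table()].
#' @param csv_path Output CSV path.
#' @param json_path Output JSON path; default swaps the extension.
#' @return `csv_path`, invisibly.
#' @export
write_tradeoff_report <- function(table, csv_path,
                                  json_path = sub("\\.[^.]*$", ".json",
                                                  csv_path)) {
  utils::write.csv(table, csv_path, row.names = FALSE)
  jsonlite::write_json(table, json_path, auto_unbox = TRUE, pretty = TRUE,
                       na = "null", digits = NA)
  invisible(csv_path)
}
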