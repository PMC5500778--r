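#' Round half away from zero
#'
#' Plain decimal rounding where .5 always rounds up in magnitude, matching
#' how percentages are conventionally printed in evaluation tables (base R's
#' `round` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Cross-tabulate cluster assignments against gold labels
#'
#' Builds the cluster-by-label contingency table scoring the distance
#' clustering: rows are cluster indices, columns the counts of pairs whose
#' gold label is OTHER (not an adverse reaction) and ADR.
#'
#' @param assigned Data.frame of pairs with columns `message_id`, `llt_id`,
#'   `disorder_pos` and `cluster`.
#' @param gold Data.frame of gold annotations with columns `message_id`,
#'   `llt_id`, `start_pos` and `label` (values `"ADR"` / `"OTHER"`).
#' @param K Number of clusters (rows); defaults to `max(assigned$cluster)`.
#' @return An `adr_contingency` object.
#' @export
contingency <- function(assigned, gold, K = NULL) {
  stopifnot(is.data.frame(assigned), is.data.frame(gold),
            all(c("message_id", "llt_id", "disorder_pos", "cluster") %in% names(assigned)),
            all(c("message_id", "llt_id", "start_pos", "label") %in% names(gold)))
  if (is.null(K)) K <- if (nrow(assigned)) max(assigned$cluster) else 1L
  key_a <- paste(assigned$message_id, assigned$llt_id, assigned$disorder_pos)
  key_g <- paste(gold$message_id, gold$llt_id, gold$start_pos)
  pos <- match(key_a, key_g)
  if (anyNA(pos)) {
    stop("unlabeled pair(s): no gold annotation for key(s) ",
         paste(utils::head(key_a[is.na(pos)], 5L), collapse = "; "),
         call. = FALSE)
  }
  lab <- toupper(gold$label[pos])
  if (!all(lab %in% c("ADR", "OTHER"))) {
    stop("gold labels must be ADR or OTHER", call. = FALSE)
  }
  other <- tabulate(assigned$cluster[lab == "OTHER"], K)
  adr <- tabulate(assigned$cluster[lab == "ADR"], K)
  contingency_from_counts(other, adr)
}

#' Build a contingency table directly from per-cluster counts
#'
#' @param other,adr Integer vectors: per-cluster counts of non-ADR and ADR
#'   pairs (same length, cluster order).
#' @return An `adr_contingency` object: matrix with columns `other`, `adr`
#'   plus total attributes.
#' @export
contingency_from_counts <- function(other, adr) {
  stopifnot(length(other) == length(adr), all(other >= 0), all(adr >= 0))
  m <- cbind(other = as.numeric(other), adr = as.numeric(adr))
  rownames(m) <- paste0("cluster", seq_len(nrow(m)))
  structure(m, class = c("adr_contingency", class(m)))
}

#' @export
print.adr_contingency <- function(x, ...) {
  m <- unclass(x)
  tot <- rowSums(m)
  pct <- ifelse(tot > 0, 100 * m[, "adr"] / tot, NaN)
  df <- data.frame(other = m[, "other"], adr = m[, "adr"], total = tot,
                   adr_pct = round_half_up(pct, 1))
  df <- rbind(df, total = c(colSums(m), sum(tot),
                            round_half_up(100 * sum(m[, "adr"]) / sum(tot), 2)))
  print(df)
  invisible(x)
}

#' Score a cluster-merge filtering strategy
#'
#' Pairs assigned to the clusters in `filter_set` are removed from the ADR
#' candidate stream (classified non-ADR). Following the convention of
#' scoring the *removal of false positives*, the positive class is the
#' filtered-out non-ADR pair: precision is the fraction of removed pairs
#' that are truly non-ADR, recall the fraction of all non-ADR pairs that
#' were removed; the reduction rate of the false-positive burden equals this
#' recall. Note this inverts the usual ADR-positive convention.
#'
#' @param table An `adr_contingency`.
#' @param filter_set Integer cluster indices to remove.
#' @param name Optional strategy name for reporting.
#' @return A `filter_report`: list with raw counts (`filtered_other`,
#'   `filtered_adr`, `kept_other`, `kept_adr`), full-precision `precision`,
#'   `recall`, `reduction`, `adr_coverage` of the kept clusters, and a
#'   `rounded` sub-list at conventional table printing precision.
#' @export
apply_strategy <- function(table, filter_set, name = NULL) {
  stopifnot(inherits(table, "adr_contingency"), length(filter_set) >= 1L)
  K <- nrow(table)
  filter_set <- sort(unique(as.integer(filter_set)))
  if (!all(filter_set %in% seq_len(K))) {
    stop("filter_set outside 1..", K, call. = FALSE)
  }
  if (length(filter_set) == K) {
    warning("filter_set removes every cluster: nothing is kept", call. = FALSE)
  }
  kept_set <- setdiff(seq_len(K), filter_set)
  m <- unclass(table)
  filtered_other <- sum(m[filter_set, "other"])
  filtered_adr <- sum(m[filter_set, "adr"])
  kept_other <- sum(m[kept_set, "other"])
  kept_adr <- sum(m[kept_set, "adr"])
  total_other <- filtered_other + kept_other
  total_adr <- filtered_adr + kept_adr
  n_filtered <- filtered_other + filtered_adr
  precision <- if (n_filtered > 0) filtered_other / n_filtered else {
    warning("no pairs filtered: precision undefined", call. = FALSE)
    NaN
  }
  recall <- if (total_other > 0) filtered_other / total_other else 0
  coverage <- adr_coverage(table, kept_set)
  structure(list(
    strategy = if (is.null(name)) paste0("filter{", paste(filter_set, collapse = ","), "}") else name,
    filter_set = filter_set, kept_set = kept_set,
    filtered_other = filtered_other, filtered_adr = filtered_adr,
    kept_other = kept_other, kept_adr = kept_adr,
    precision = precision, recall = recall, reduction = recall,
    adr_coverage = coverage,
    rounded = list(precision_pct = round_half_up(100 * precision, 1),
                   recall_pct = round_half_up(100 * recall, 2),
                   reduction_pct = round_half_up(100 * recall, 2),
                   adr_coverage_pct = round_half_up(100 * coverage, 1))),
    class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter strategy %s>\n", x$strategy))
  cat(sprintf("  removed: %d non-ADR + %d ADR; kept: %d non-ADR + %d ADR\n",
              x$filtered_other, x$filtered_adr, x$kept_other, x$kept_adr))
  cat(sprintf("  precision %.4f%%  recall/reduction %.4f%%  ADR coverage of kept %.4f%%\n",
              100 * x$precision, 100 * x$recall, 100 * x$adr_coverage))
  invisible(x)
}

#' Fraction of true ADRs retained by the kept clusters
#'
#' @param table An `adr_contingency`.
#' @param kept_set Integer cluster indices retained (complement of the
#'   filter set).
#' @return ADRs in kept clusters / total ADRs (NaN with a warning when no
#'   ADR exists).
#' @export
adr_coverage <- function(table, kept_set) {
  stopifnot(inherits(table, "adr_contingency"))
  m <- unclass(table)
  total_adr <- sum(m[, "adr"])
  if (total_adr == 0) {
    warning("no ADR in table: coverage undefined", call. = FALSE)
    return(NaN)
  }
  kept_set <- intersect(seq_len(nrow(m)), kept_set)
  sum(m[kept_set, "adr"]) / total_adr
}

#' Read a contingency table from CSV
#'
#' Columns: `cluster, other, adr`, one row per cluster in cluster order. The
#' package ships a reference fixture
#' (`system.file("extdata", "table1_contingency.csv", package = "adrdist")`)
#' holding the published cluster-by-label counts used by the evaluation
#' examples and tests.
#'
#' @param path Path to the CSV.
#' @return An `adr_contingency`.
#' @export
read_contingency_csv <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8-BOM")
  miss <- setdiff(c("cluster", "other", "adr"), names(df))
  if (length(miss)) {
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- df[order(as.integer(df$cluster)), ]
  contingency_from_counts(as.numeric(df$other), as.numeric(df$adr))
}
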