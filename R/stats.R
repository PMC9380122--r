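#' Load the packaged per-patient margin table
#'
#' Thirty patients treated with percutaneous thermal ablation of colorectal
#' liver metastases: 14 who later developed local tumor progression (group
#' \code{"LTP"}) and 16 who remained progression-free (\code{"LTP-free"}).
#' For each patient the table stores, exactly as printed in the source
#' report, the 3D minimum distance to agreement (DTA) between the mapped
#' tumor and the ablation zone, and the percentage and absolute volume (cc)
#' of tumor mapped outside the ablation zone, under rigid and deformable
#' registration. The DTA columns are stored verbatim with no unit
#' conversion.
#'
#' @return data frame with columns \code{patient_id}, \code{group},
#'   \code{dta_rigid}, \code{dta_deformed}, \code{pct_rigid},
#'   \code{pct_deformed}, \code{cc_rigid}, \code{cc_deformed}.
#' @export
load_margin_table <- function() {
  path <- system.file("extdata", "patient_margins.csv",
                      package = "ablmargin", mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(nrow(df) == 30, sum(df$group == "LTP") == 14,
            sum(df$group == "LTP-free") == 16)
  df
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum U statistic with midranks for ties. The two-sided p-value is
#' exact (full enumeration of the rank-sum distribution) when
#' \code{length(a) * length(b) <= 400} and there are no ties; otherwise the
#' normal approximation with tie correction and continuity correction is
#' used. Chosen over a t-test because minimum-margin data are unpaired and
#' truncated at 0 mm (not continuous).
#'
#' @param values_a,values_b numeric vectors (both nonempty).
#' @return list with \code{U} (for the first sample), \code{p} (two-sided),
#'   and \code{method}.
#' @export
mann_whitney_u <- function(values_a, values_b) {
  na <- length(values_a); nb <- length(values_b)
  if (na == 0 || nb == 0) stop("both groups must be nonempty")
  r <- rank(c(values_a, values_b))          # midranks
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(c(values_a, values_b)) > 0
  if (!ties && na * nb <= 400) {
    # exact distribution of the rank sum by dynamic programming
    counts <- mwu_exact_counts(na, nb)      # P(U = u), u = 0..na*nb
    tot <- sum(counts)
    lo <- sum(counts[seq_len(U + 1)])       # P(U <= u)
    hi <- sum(counts[(U + 1):length(counts)])  # P(U >= u)
    p <- min(1, 2 * min(lo, hi) / tot)
    method <- "exact"
  } else {
    mu <- na * nb / 2
    n <- na + nb
    tie_tab <- table(c(values_a, values_b))
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma <- sqrt(na * nb / 12 * ((n + 1) - tie_term))
    z <- (U - mu - sign(U - mu) * 0.5) / sigma   # continuity correction
    if (sigma == 0) z <- 0
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation (tie-corrected)"
  }
  list(U = U, p = p, method = method)
}

# number of size-na subsets of ranks 1..(na+nb) attaining each U value
# (u = 0..na*nb). U counts are the partitions of u into at most na parts
# each <= nb: c(u; m, n) = c(u; m, n-1) + c(u - n; m - 1, n).
mwu_exact_counts <- function(na, nb) {
  maxu <- na * nb
  prev <- matrix(0, na + 1, maxu + 1)
  prev[, 1] <- 1                      # n = 0: only u = 0 attainable
  for (n in seq_len(nb)) {
    cur <- matrix(0, na + 1, maxu + 1)
    cur[1, 1] <- 1                    # m = 0
    for (m in seq_len(na)) {
      cur[m + 1, ] <- prev[m + 1, ]
      idx <- (n + 1):(maxu + 1)
      cur[m + 1, idx] <- cur[m + 1, idx] + cur[m, idx - n]
    }
    prev <- cur
  }
  prev[na + 1, ]
}

#' ROC AUC for separating progression-free from progressing patients
#'
#' Rank-sum (Mann-Whitney) formulation of the area under the ROC curve:
#' the probability that a randomly chosen patient with \code{labels ==
#' positive} scores higher than a randomly chosen other patient, ties
#' counted 1/2. With minimum-margin scores and \code{positive =
#' "LTP-free"}, larger margins indicate freedom from progression.
#'
#' @param scores numeric scores.
#' @param labels vector with exactly two classes.
#' @param positive the label treated as the higher-scoring class (default
#'   \code{"LTP-free"}).
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels, positive = "LTP-free") {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Group summary of a margin-table column
#'
#' Mean, population standard deviation (divisor N), median, min and max of
#' one numeric column, per group and pooled. The population standard
#' deviation matches the convention of the packaged table's summary rows.
#'
#' @param records data frame from \code{\link{load_margin_table}} (or
#'   compatible).
#' @param column column name to summarize.
#' @param grouping \code{"group"} for per-group plus pooled summaries, or
#'   \code{"pooled"} for pooled only.
#' @return data frame with rows per group (and \code{"pooled"}) and columns
#'   \code{mean}, \code{sd}, \code{median}, \code{min}, \code{max}, \code{n}.
#' @export
summarize_margins <- function(records, column, grouping = c("group", "pooled")) {
  grouping <- match.arg(grouping)
  if (!column %in% names(records)) stop("unknown column: ", column)
  x <- records[[column]]
  if (length(x) == 0) stop("empty selection")
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  one <- function(v, label) data.frame(
    group = label, mean = mean(v), sd = pop_sd(v), median = median(v),
    min = min(v), max = max(v), n = length(v))
  out <- one(x, "pooled")
  if (grouping == "group" && "group" %in% names(records)) {
    per <- do.call(rbind, lapply(split(x, records$group),
                                 function(v) one(v, "")))
    per$group <- names(split(x, records$group))
    out <- rbind(per, out)
  }
  rownames(out) <- NULL
  out
}

#' Full statistics report for a margin table
#'
#' Reproduces the group comparisons for a per-patient margin table: group
#' and pooled summaries of every numeric column, Mann-Whitney U tests of
#' LTP vs LTP-free for the rigid and deformable minimum DTA, and ROC AUCs
#' for identifying progression from the minimum DTA.
#'
#' @param records margin table (default the packaged one).
#' @return list with \code{summaries}, \code{tests}, \code{auc}.
#' @export
margin_stats_report <- function(records = load_margin_table()) {
  num_cols <- setdiff(names(records)[vapply(records, is.numeric, TRUE)],
                      "patient_id")
  summaries <- lapply(num_cols, function(cl)
    summarize_margins(records, cl, "group"))
  names(summaries) <- num_cols
  a <- records[records$group == "LTP", ]
  b <- records[records$group == "LTP-free", ]
  tests <- list(
    dta_rigid = mann_whitney_u(a$dta_rigid, b$dta_rigid),
    dta_deformed = mann_whitney_u(a$dta_deformed, b$dta_deformed))
  auc <- c(rigid = roc_auc(records$dta_rigid, records$group),
           deformed = roc_auc(records$dta_deformed, records$group))
  list(summaries = summaries, tests = tests, auc = auc)
}
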