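#' Hypergeometric gene-set over-representation
#'
#' For each set, the upper-tail hypergeometric probability of observing at
#' least the actual overlap between the query and the set, given the
#' universe; Benjamini-Hochberg adjustment across all tested sets.
#'
#' @param query Character vector of query gene symbols (subset of universe).
#' @param universe Character vector of background gene symbols.
#' @param sets Named list of gene-set character vectors (e.g. [read_gmt()]);
#'   each set is intersected with the universe before testing.
#' @param fdr_cutoff Significance cutoff on the adjusted p (default 0.05).
#' @return data.frame (class `enrichment_result`): set, category, overlap,
#'   set_size, query_size, universe_size, p, fdr, significant; sorted by p.
#' @export
hypergeometric_enrichment <- function(query, universe, sets, fdr_cutoff = 0.05) {
  query <- unique(query)
  universe <- unique(universe)
  if (!length(query) || !length(universe)) stop("empty query or universe")
  extra <- setdiff(query, universe)
  if (length(extra)) {
    stop("query gene(s) not in universe: ", paste(utils::head(extra, 5L), collapse = ", "))
  }
  cat_tags <- attr(sets, "category")
  if (is.null(cat_tags)) cat_tags <- stats::setNames(rep(NA_character_, length(sets)), names(sets))
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    K <- length(s)
    if (K == 0L) return(NULL)
    x <- length(intersect(query, s))
    p <- stats::phyper(x - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, category = unname(cat_tags[nm]), overlap = x,
               set_size = K, query_size = n, universe_size = N, p = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) {
    return(structure(data.frame(set = character(), category = character(),
                                overlap = integer(), set_size = integer(),
                                query_size = integer(), universe_size = integer(),
                                p = numeric(), fdr = numeric(),
                                significant = logical()),
                     class = c("enrichment_result", "data.frame")))
  }
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p)
  out$significant <- out$fdr < fdr_cutoff
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_result", "data.frame"))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control with monotonicity enforcement.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values (same order as input).
#' @export
bh_adjust <- function(p) {
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Median dichotomization of an expression vector
#'
#' "high" = strictly above the median; ties at the median go to "low".
#'
#' @param x Numeric vector, >= 4 values, not all identical.
#' @return Factor with levels low, high (low first).
#' @export
median_split <- function(x) {
  if (length(x) < 4L) stop("median split needs >= 4 samples")
  if (diff(range(x)) == 0) stop("all values identical; cannot split")
  med <- stats::median(x)
  factor(ifelse(x > med, "high", "low"), levels = c("low", "high"))
}

#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimator with right censoring.
#'
#' @param time Non-negative follow-up times.
#' @param event 1 = event, 0 = censored.
#' @param group Group labels.
#' @return data.frame with columns group, time, n_risk, n_event, survival;
#'   one row per distinct time per group, beginning at time 0 with survival 1.
#' @export
km_curve <- function(time, event, group) {
  if (any(time < 0)) stop("negative survival time")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  group <- as.factor(group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  strata <- if (is.null(fit$strata)) {
    rep(levels(group)[1L], length(fit$time))
  } else {
    rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  pieces <- lapply(unique(strata), function(g) {
    i <- strata == g
    data.frame(group = g,
               time = c(0, fit$time[i]),
               n_risk = c(max(fit$n.risk[i]), fit$n.risk[i]),
               n_event = c(0, fit$n.event[i]),
               survival = c(1, fit$surv[i]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Two-group log-rank test
#'
#' Mantel-Haenszel log-rank: at each distinct event time the observed minus
#' expected events in group 1 are accumulated with the hypergeometric
#' variance; the statistic is chi-squared on 1 df.
#'
#' @param time Non-negative follow-up times.
#' @param event 1 = event, 0 = censored; at least one event overall.
#' @param group Exactly two non-empty groups.
#' @return List of class `logrank_result`: `chisq`, `p`, `n` (per group),
#'   `observed` (events per group), `expected` (expected events per group).
#' @export
logrank_test <- function(time, event, group) {
  if (any(time < 0)) stop("negative survival time")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L) stop("log-rank test needs exactly 2 non-empty groups")
  if (sum(event) < 1L) stop("log-rank test needs >= 1 event")
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  chisq <- unname(sd_fit$chisq)
  structure(list(chisq = chisq,
                 p = stats::pchisq(chisq, df = 1L, lower.tail = FALSE),
                 n = stats::setNames(as.integer(sd_fit$n), levels(group)),
                 observed = stats::setNames(as.numeric(sd_fit$obs), levels(group)),
                 expected = stats::setNames(as.numeric(sd_fit$exp), levels(group))),
            class = "logrank_result")
}
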