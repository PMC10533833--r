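# Composite scale construction and per-wave descriptive tables.

#' Internal consistency of a multi-item measure
#'
#' Pearson correlation for two items, Cronbach's alpha
#' \eqn{k/(k-1) (1 - \sum s_i^2 / s_T^2)} for more than two.
#'
#' @param items numeric matrix (n rows, k >= 2 item columns), no missing
#'   values, n >= 3.
#' @return the consistency statistic.
#' @export
internal_consistency <- function(items) {
  items <- as.matrix(items)
  k <- ncol(items)
  if (k < 2L) stop("need at least 2 items")
  if (nrow(items) < 3L) stop("need at least 3 observations")
  if (anyNA(items)) stop("missing values in items")
  v <- apply(items, 2L, var)
  if (any(v == 0)) {
    nm <- colnames(items)
    if (is.null(nm)) nm <- paste0("item", seq_len(k))
    stop("zero-variance item: ", paste(nm[v == 0], collapse = ", "))
  }
  if (k == 2L) {
    cor(items[, 1], items[, 2])
  } else {
    k / (k - 1) * (1 - sum(v) / var(rowSums(items)))
  }
}

#' Combine multi-item measures into mean-score composites
#'
#' Each composite in \code{bank} (a named list mapping composite code to
#' item column names) is formed as the row mean of its items, but only if
#' the items' internal consistency exceeds \code{threshold}; otherwise the
#' items are kept and the composite is flagged as not combined.
#'
#' @param panel a data frame containing the item columns.
#' @param bank named list: composite code -> character vector of item
#'   columns.
#' @param threshold consistency gate in (0, 1), default 0.7.
#' @return the panel with composite columns added (items of combined
#'   composites dropped); attribute \code{"not_combined"} lists composites
#'   that failed the gate, and a warning is raised for each.
#' @export
combine_items <- function(panel, bank, threshold = 0.7) {
  stopifnot(threshold > 0, threshold < 1)
  all_items <- unlist(bank)
  if (anyDuplicated(all_items)) stop("an item appears in two composites")
  missing <- setdiff(all_items, names(panel))
  if (length(missing)) stop("items absent from panel: ",
                            paste(missing, collapse = ", "))
  not_combined <- character(0)
  for (comp in names(bank)) {
    cols <- bank[[comp]]
    stat <- internal_consistency(as.matrix(as.data.frame(panel)[, cols]))
    if (stat > threshold) {
      panel[[comp]] <- rowMeans(as.data.frame(panel)[, cols])
      panel <- panel[, setdiff(names(panel), cols)]
    } else {
      not_combined <- c(not_combined, comp)
      warning("composite '", comp, "' not combined (consistency ",
              signif(stat, 3), " <= ", threshold, ")")
    }
  }
  attr(panel, "not_combined") <- not_combined
  panel
}

#' Default multi-item bank of the questionnaire
#'
#' Maps the composite node codes to their raw item columns: the HIV risk
#' perception composite (4 items) and the three 2-item self-efficacy
#' composites.
#'
#' @return named list of item-column vectors.
#' @export
default_item_bank <- function() {
  list(riskHIV = paste0("riskHIV_", 1:4),
       prep20 = paste0("prep20_", 1:2),
       prep21 = paste0("prep21_", 1:2),
       vls9 = paste0("vls9_", 1:2))
}

#' Per-wave uptake table of HIV prevention strategies
#'
#' For each wave: N and count/percentage of the ten strategy categories —
#' any strategy (PrEP, VLS or condom), condom use, PrEP, VLS, no
#' prevention, any biomedical (PrEP or VLS), only PrEP, only VLS, both,
#' and no biomedical. Percentages are rounded half-away-from-zero to
#' integers for display; unrounded values are kept in \code{pct_raw}.
#'
#' @param panel a panel with 0/1 columns \code{PrEP}, \code{VLS},
#'   \code{condom} and a \code{wave} column.
#' @return data frame (wave, category, n, N, pct, pct_raw).
#' @export
describe_uptake <- function(panel) {
  need <- c("PrEP", "VLS", "condom", "wave")
  missing <- setdiff(need, names(panel))
  if (length(missing)) stop("panel lacks columns: ",
                            paste(missing, collapse = ", "))
  df <- as.data.frame(panel)
  out <- lapply(sort(unique(df$wave)), function(wv) {
    d <- df[df$wave == wv, ]
    N <- nrow(d)
    prep <- d$PrEP == 1; vls <- d$VLS == 1; con <- d$condom == 1
    n <- c(any_strategy = sum(prep | vls | con),
           condom = sum(con),
           prep = sum(prep),
           vls = sum(vls),
           no_prevention = sum(!(prep | vls | con)),
           any_biomedical = sum(prep | vls),
           only_prep = sum(prep & !vls),
           only_vls = sum(vls & !prep),
           both = sum(prep & vls),
           no_biomedical = sum(!(prep | vls)))
    pct_raw <- if (N > 0) 100 * n / N else rep(NA_real_, length(n))
    data.frame(wave = wv, category = names(n), n = as.integer(n), N = N,
               pct = round_half_away(pct_raw), pct_raw = pct_raw,
               row.names = NULL)
  })
  do.call(rbind, out)
}

#' Per-wave mean and SD of belief nodes
#'
#' Sample mean and SD (n-1 denominator) per gaussian node per wave;
#' display-rounded values to one decimal are included alongside the raw
#' statistics.
#'
#' @param panel a panel data frame with a \code{wave} column.
#' @param nodes node codes to summarize; defaults to the gaussian nodes of
#'   the attached roster (or all numeric non-id columns).
#' @return data frame (wave, node, mean, sd, mean_display, sd_display).
#' @export
describe_beliefs <- function(panel, nodes = NULL) {
  df <- as.data.frame(panel)
  if (is.null(nodes)) {
    roster <- attr(panel, "roster")
    nodes <- if (!is.null(roster)) gaussian_codes(roster) else {
      setdiff(names(df)[vapply(df, is.numeric, TRUE)],
              c("participant_id", "wave", "cas", "condom"))
    }
  }
  out <- lapply(sort(unique(df$wave)), function(wv) {
    d <- df[df$wave == wv, nodes, drop = FALSE]
    data.frame(wave = wv, node = nodes,
               mean = colMeans(d), sd = apply(d, 2L, sd), row.names = NULL)
  })
  out <- do.call(rbind, out)
  out$mean_display <- round_half_away(out$mean, 1)
  out$sd_display <- round_half_away(out$sd, 1)
  out
}

#' Summary of a printed visit-count distribution
#'
#' Recomputes the totals and quantiles implied by counts of participants
#' attending 1..K visits: total participants, total visits, and the median
#' and interquartile range of visits per participant.
#'
#' @param counts integer vector; \code{counts[k]} participants with k
#'   visits.
#' @return list with \code{n_participants}, \code{n_visits},
#'   \code{median}, \code{q25}, \code{q75}.
#' @export
visit_count_summary <- function(counts) {
  k <- seq_along(counts)
  x <- rep(k, counts)
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 2, names = FALSE)
  list(n_participants = sum(counts), n_visits = sum(k * counts),
       median = q[2], q25 = q[1], q75 = q[3])
}
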