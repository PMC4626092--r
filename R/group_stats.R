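#' Aggregate per-image measurements to one value per animal
#'
#' The animal (not the image) is the unit of inference: each animal's
#' value is the arithmetic mean of its image values, so unbalanced image
#' counts do not weight animals unequally in group summaries.
#'
#' @param df data.frame with columns `animal_id`, `group`, `metric`,
#'   `value` (one row per image measurement).
#' @return data.frame with one row per animal x metric: `animal_id`,
#'   `group`, `metric`, `value`, `n_images`.
#' @export
aggregate_per_animal <- function(df) {
  need <- c("animal_id", "group", "metric", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(is.na(df$animal_id)) || any(!nzchar(as.character(df$animal_id))))
    stop("every image row needs an animal_id")
  key <- interaction(df$animal_id, df$metric, drop = TRUE)
  out <- do.call(rbind, lapply(split(df, key), function(s) {
    if (length(unique(s$group)) != 1L)
      stop("animal '", s$animal_id[1L], "' appears in multiple groups")
    data.frame(animal_id = s$animal_id[1L], group = s$group[1L],
               metric = s$metric[1L], value = mean(s$value),
               n_images = nrow(s), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$metric, out$group, out$animal_id), ]
}

#' Normalize animal values to the control-group mean
#'
#' Divides every animal value by the mean of the control group, so the
#' control group's relative mean is 1 by construction; per-group SEM is
#' computed on the normalized values (SD / sqrt(n)).
#'
#' @param df per-animal data.frame (`animal_id`, `group`, `value`; a
#'   single metric).
#' @param control_group label of the reference group.
#' @return list with `values` (df plus `relative_value`) and `summary`
#'   (per-group n, relative mean, SEM).
#' @export
relative_to_control <- function(df, control_group) {
  stopifnot(all(c("animal_id", "group", "value") %in% names(df)))
  ctrl <- df$value[df$group == control_group]
  if (length(ctrl) == 0L) stop("control group '", control_group, "' is empty")
  cm <- mean(ctrl)
  if (cm == 0) stop("degenerate normalization: control mean is 0")
  df$relative_value <- df$value / cm
  sm <- do.call(rbind, lapply(split(df, df$group), function(s)
    data.frame(group = s$group[1L], n = nrow(s),
               relative_mean = mean(s$relative_value),
               sem = stats::sd(s$relative_value) / sqrt(nrow(s)),
               stringsAsFactors = FALSE)))
  rownames(sm) <- NULL
  list(values = df, summary = sm, control_group = control_group,
       control_mean = cm)
}

#' Unpaired two-sample t test
#'
#' Student's pooled-variance t by default (the period-typical Prism
#' default for "unpaired t test"); Welch's unequal-variance form via
#' `var_equal = FALSE`. Degenerate zero-variance inputs return p = 1 when
#' the means agree and p = 0 (with a warning) when they differ.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @param var_equal pool the variances (default TRUE).
#' @return list with `t`, `df`, `p`.
#' @export
unpaired_t <- function(a, b, var_equal = TRUE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  md <- mean(a) - mean(b)
  if (va == 0 && vb == 0) {
    if (md == 0) return(list(t = 0, df = na + nb - 2, p = 1))
    warning("zero variance with unequal means: p -> 0")
    return(list(t = sign(md) * Inf, df = na + nb - 2, p = 0))
  }
  if (var_equal) {
    df <- na + nb - 2
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
    se <- sqrt(sp2 * (1 / na + 1 / nb))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- md / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' Fixed-effects one-way ANOVA (F test) followed by Tukey-Kramer pairwise
#' comparisons using the studentized-range distribution at the ANOVA's
#' error degrees of freedom.
#'
#' @param groups named list of >= 3 numeric vectors, each of length >= 2.
#' @return list with `F`, `df` (c(between, within)), `p`, and `pairwise`
#'   (data.frame: group1, group2, diff, p_adj).
#' @export
anova_tukey <- function(groups) {
  if (!is.list(groups) || length(groups) < 3L)
    stop("need >= 3 groups; use unpaired_t() for two")
  if (any(vapply(groups, length, 0L) < 2L))
    stop("every group needs >= 2 observations")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  k <- length(groups)
  n <- vapply(groups, length, 0L)
  N <- sum(n)
  means <- vapply(groups, mean, 0)
  grand <- sum(unlist(groups)) / N
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  dfb <- k - 1L
  dfw <- N - k
  msw <- ssw / dfw
  if (msw == 0) {
    warning("zero within-group variance")
    Fv <- if (ssb == 0) 0 else Inf
    p <- if (ssb == 0) 1 else 0
  } else {
    Fv <- (ssb / dfb) / msw
    p <- stats::pf(Fv, dfb, dfw, lower.tail = FALSE)
  }
  cmb <- utils::combn(k, 2L)
  pw <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(t) {
    i <- cmb[1L, t]; j <- cmb[2L, t]
    diff <- means[j] - means[i]
    se <- sqrt(msw / 2 * (1 / n[i] + 1 / n[j]))  # Tukey-Kramer
    q <- if (se > 0) abs(diff) / se else if (diff == 0) 0 else Inf
    p_adj <- if (is.infinite(q)) 0 else
      stats::ptukey(q, nmeans = k, df = dfw, lower.tail = FALSE)
    data.frame(group1 = names(groups)[i], group2 = names(groups)[j],
               diff = unname(diff), p_adj = p_adj,
               stringsAsFactors = FALSE)
  }))
  rownames(pw) <- NULL
  list(F = Fv, df = c(between = dfb, within = dfw), p = p, pairwise = pw)
}

#' Linear correlation (R-squared)
#'
#' Squared Pearson correlation with a two-sided p value for the
#' zero-correlation null.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `r_squared`, `r`, `p`.
#' @export
linear_r2 <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate correlation: constant input")
  r <- stats::cor(x, y)
  n <- length(x)
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r_squared = r^2, r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

#' Build a Ct table for relative qPCR quantification
#'
#' @param df data.frame with columns `sample_id`, `group`, `gene`,
#'   `replicate`, `ct` (technical replicates, typically triplicate).
#' @param normalizers character vector of reference gene names (e.g.
#'   `"Actb"`); must be non-empty and present in the table.
#' @param control_group label of the reference cohort.
#' @return a `ct_table` list.
#' @export
ct_table <- function(df, normalizers, control_group) {
  need <- c("sample_id", "group", "gene", "replicate", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("Ct table missing column(s): ", paste(miss, collapse = ", "))
  if (length(normalizers) < 1L) stop("need at least one normalizer gene")
  if (!all(normalizers %in% df$gene))
    stop("normalizer gene(s) absent from table: ",
         paste(setdiff(normalizers, df$gene), collapse = ", "))
  if (!control_group %in% df$group)
    stop("control group '", control_group, "' absent from table")
  if (any(!is.finite(df$ct) | df$ct <= 0))
    stop("nonpositive or non-finite Ct values (geometric mean undefined)")
  structure(list(data = df, normalizers = normalizers,
                 control_group = control_group), class = "ct_table")
}

geo_mean <- function(x) exp(mean(log(x)))

#' Delta-delta-Ct fold changes with a 2-SD differential-expression call
#'
#' Per sample and gene of interest: Ct is the mean of the successful
#' replicates; delta Ct = Ct(gene) - geometric mean of the normalizer
#' Cts; delta-delta Ct = delta Ct - mean delta Ct of the control group.
#' The fold change is reported with the signed convention:
#' `2^(-ddCt)` when up-regulated (fold >= 1) and `-2^(ddCt)` when
#' down-regulated; the unsigned `2^(-ddCt)` column is also emitted. A
#' sample-gene is flagged DE when its signed fold lies more than two
#' control-group standard deviations from the control-group mean fold.
#'
#' @param ct a [ct_table()].
#' @return a data.frame with one row per sample x gene of interest:
#'   `sample_id`, `group`, `gene`, `ct_mean`, `delta_ct`,
#'   `delta_delta_ct`, `fold_change` (signed), `fold_unsigned`, `de_flag`.
#' @export
ddct_fold_change <- function(ct) {
  stopifnot(inherits(ct, "ct_table"))
  df <- ct$data
  # replicate-mean Ct per sample x gene
  key <- interaction(df$sample_id, df$gene, drop = TRUE)
  agg <- do.call(rbind, lapply(split(df, key), function(s)
    data.frame(sample_id = s$sample_id[1L], group = s$group[1L],
               gene = s$gene[1L], ct_mean = mean(s$ct),
               stringsAsFactors = FALSE)))
  samples <- unique(agg$sample_id)
  goi <- setdiff(unique(agg$gene), ct$normalizers)
  rows <- list()
  for (s in samples) {
    sub <- agg[agg$sample_id == s, ]
    norm_ct <- sub$ct_mean[match(ct$normalizers, sub$gene)]
    if (any(is.na(norm_ct))) {
      warning("sample '", s, "' lacks normalizer Ct; dropped")
      next
    }
    nf <- geo_mean(norm_ct)
    for (g in goi) {
      cg <- sub$ct_mean[sub$gene == g]
      if (length(cg) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, group = sub$group[1L], gene = g, ct_mean = cg,
        delta_ct = cg - nf, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no gene-of-interest measurements")
  out <- do.call(rbind, lapply(split(res, res$gene), function(s) {
    ctrl_dct <- s$delta_ct[s$group == ct$control_group]
    if (length(ctrl_dct) < 2L)
      stop("control group needs >= 2 samples with gene '", s$gene[1L], "'")
    s$delta_delta_ct <- s$delta_ct - mean(ctrl_dct)
    s$fold_unsigned <- 2^(-s$delta_delta_ct)
    s$fold_change <- ifelse(s$fold_unsigned >= 1,
                            s$fold_unsigned, -2^s$delta_delta_ct)
    ctrl_fold <- s$fold_change[s$group == ct$control_group]
    mu <- mean(ctrl_fold); sdv <- stats::sd(ctrl_fold)
    s$de_flag <- abs(s$fold_change - mu) > 2 * sdv
    s
  }))
  rownames(out) <- NULL
  out[order(out$gene, out$group, out$sample_id), ]
}
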