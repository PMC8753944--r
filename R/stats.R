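# Verification, validation, replication sizing, and the scenario-comparison
# statistics: blocked two-factor ANOVA on per-replication mean satisfaction
# and Tukey HSD with a compact letter display.

#' Verification: deterministic no-queue equivalence
#'
#' Runs one patient of each type (old status) through the model with constant
#' (mean) service times and effectively unlimited capacity, and compares the
#' simulated length of stay with the manual sum of the mean service times
#' along the type's flow path. The two must agree exactly; a mismatch
#' indicates a logic bug in the flow model.
#'
#' @param cfg a `frontflow_config` (defaults to [default_config()]).
#' @return data.frame with `type`, `manual_min`, `simulated_min`, `equal`.
#' @export
verify_model <- function(cfg = default_config()) {
  ample <- cfg$schedule
  ample[c("N", "N2", if (cfg$policy == "one_stop") "M" else paste0("M", 1:4)), ] <- 100L
  cfg$schedule <- ample
  out <- lapply(1:4, function(ty) {
    path <- flow_path(ty, is_new = FALSE)
    manual <- sum(vapply(path, function(st) {
      nm <- if (st == "mr") paste0("mr_type", ty) else st
      mean_service(cfg$services[[nm]])
    }, numeric(1))) / 60
    rec <- run_replication(cfg, seed = 1L, deterministic = TRUE,
                           arrivals = data.frame(ticket_time = 0, type = ty,
                                                 is_new = FALSE))
    sim <- rec$patients$los[1]
    data.frame(type = ty, manual_min = manual, simulated_min = sim,
               equal = abs(manual - sim) < 1e-9)
  })
  do.call(rbind, out)
}

#' Welch two-sample t-test from summary statistics
#'
#' Validation compares the simulated mean length of stay per patient type
#' with the observed statistics from the real system, using an
#' unequal-variance (Welch) two-sided t-test on the summarized samples.
#'
#' @param a,b lists with `mean`, `sd`, `n` (each `n >= 2`).
#' @param alpha significance level for the rejection flag (default 0.05).
#' @return list with `t`, `df`, `p_value`, `reject_at_95`.
#' @export
welch_t <- function(a, b, alpha = 0.05) {
  stopifnot(a$n >= 2, b$n >= 2, a$sd >= 0, b$sd >= 0)
  va <- a$sd^2 / a$n
  vb <- b$sd^2 / b$n
  diff <- a$mean - b$mean
  if (va + vb == 0) {
    t_stat <- if (diff == 0) 0 else Inf * sign(diff)
    p <- if (diff == 0) 1 else 0
    df <- a$n + b$n - 2
  } else {
    t_stat <- diff / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
    p <- 2 * stats::pt(-abs(t_stat), df)
  }
  list(t = t_stat, df = df, p_value = p, reject_at_95 = p < alpha)
}

#' Observed length-of-stay reference statistics
#'
#' The collected per-type LOS statistics of the case study, used as the
#' validation reference: mean and SD in minutes with the observed sample
#' sizes.
#'
#' @return data.frame with `type`, `mean`, `sd`, `n`.
#' @export
reference_los_stats <- function() {
  data.frame(
    type = 1:4,
    mean = c(56.47, 25.52, 38.89, 53.86),
    sd = c(41.90, 25.93, 22.38, 34.90),
    n = c(167, 79, 46, 73)
  )
}

#' Validate simulated LOS against reference statistics
#'
#' Simulates `replications` days, summarizes the per-type LOS and runs
#' [welch_t()] against the reference. With a 95% confidence level, p-values
#' at or above 0.05 mean the simulated and observed means are statistically
#' indistinguishable.
#'
#' @param cfg a `frontflow_config`.
#' @param reference reference stats as from [reference_los_stats()].
#' @param replications number of simulated days pooled (default 8).
#' @param seed base seed.
#' @return data.frame with per-type simulated stats, `t`, `p_value` and the
#'   validity flag (`valid = !reject`).
#' @export
validate_model <- function(cfg = default_config(),
                           reference = reference_los_stats(),
                           replications = 8L, seed = 1L) {
  los_by_type <- vector("list", 4)
  for (r in seq_len(replications)) {
    rec <- run_replication(cfg, seed = seed + r - 1L)
    for (ty in 1:4) {
      los_by_type[[ty]] <- c(los_by_type[[ty]],
                             rec$patients$los[rec$patients$type == ty])
    }
  }
  do.call(rbind, lapply(1:4, function(ty) {
    x <- los_by_type[[ty]]
    ref <- reference[reference$type == ty, ]
    tt <- welch_t(list(mean = ref$mean, sd = ref$sd, n = ref$n),
                  list(mean = mean(x), sd = stats::sd(x), n = length(x)))
    data.frame(type = ty, ref_mean = ref$mean, sim_mean = mean(x),
               sim_sd = stats::sd(x), sim_n = length(x),
               t = tt$t, p_value = tt$p_value, valid = !tt$reject_at_95)
  }))
}

#' Replication count for a relative-error target
#'
#' From a pilot set of per-replication means, computes the 95% t-based
#' confidence half-width and its ratio to the mean, then projects the
#' half-width as proportional to `1/sqrt(n)` to find the smallest replication
#' count meeting the target relative error (5% in the case study). If the
#' pilot already meets the target, the pilot count is kept.
#'
#' @param pilot_means numeric vector of per-replication means (length >= 2).
#' @param target target relative error (half-width / mean), e.g. 0.05.
#' @return list with `n0`, `mean`, `half_width`, `relative_error`,
#'   `required_n`.
#' @export
required_replications <- function(pilot_means, target = 0.05) {
  n0 <- length(pilot_means)
  stopifnot(n0 >= 2)
  if (target <= 0) stop("target relative error must be positive", call. = FALSE)
  m <- mean(pilot_means)
  if (m == 0) stop("zero mean: relative error undefined", call. = FALSE)
  hw <- stats::qt(0.975, n0 - 1) * stats::sd(pilot_means) / sqrt(n0)
  rel <- hw / abs(m)
  required <- if (rel <= target) n0 else ceiling(n0 * (rel / target)^2)
  list(n0 = n0, mean = m, half_width = hw, relative_error = rel,
       required_n = required)
}

#' Blocked two-factor ANOVA on satisfaction responses
#'
#' Fixed-effects ANOVA of the per-replication mean satisfaction with main
#' effects for the case (weight setting), the scenario (routing policy), the
#' replication as a block, and the case-by-scenario interaction. The layout
#' must be completely crossed. With a constant response all sums of squares
#' vanish; F is reported as `NA` and p as 1 (no evidence of any effect).
#'
#' @param responses data.frame with columns `case`, `scenario`,
#'   `replication`, `satisfaction`.
#' @return data.frame with rows Case, Scenario, Replication, Case:Scenario,
#'   Error, Total and columns `term`, `df`, `adj_ss`, `adj_ms`, `f`, `p`.
#' @export
anova_blocked <- function(responses) {
  need <- c("case", "scenario", "replication", "satisfaction")
  stopifnot(all(need %in% names(responses)))
  d <- data.frame(case = factor(responses$case),
                  scenario = factor(responses$scenario),
                  replication = factor(responses$replication),
                  satisfaction = responses$satisfaction)
  counts <- table(d$case, d$scenario, d$replication)
  if (any(counts != 1)) {
    stop("anova_blocked: layout must be completely crossed with one ",
         "response per (case, scenario, replication) cell", call. = FALSE)
  }
  fit <- stats::aov(satisfaction ~ case + scenario + replication +
                      case:scenario, data = d)
  tab <- summary(fit)[[1]]
  rn <- trimws(rownames(tab))
  label <- c(case = "Case", scenario = "Scenario",
             replication = "Replication", `case:scenario` = "Case:Scenario",
             Residuals = "Error")
  out <- data.frame(term = unname(label[rn]), df = tab$Df,
                    adj_ss = tab$`Sum Sq`, adj_ms = tab$`Mean Sq`,
                    f = tab$`F value`, p = tab$`Pr(>F)`)
  zero_var <- sum(tab$`Sum Sq`) < 1e-12
  if (zero_var) {
    out$f <- NA_real_
    out$p <- ifelse(out$term == "Error", NA_real_, 1)
  }
  out <- rbind(out, data.frame(term = "Total", df = sum(out$df),
                               adj_ss = sum(out$adj_ss), adj_ms = NA_real_,
                               f = NA_real_, p = NA_real_))
  rownames(out) <- NULL
  out
}

#' Tukey HSD compact letter display
#'
#' All pairwise Tukey honest-significant-difference comparisons of the group
#' means, followed by the insert-and-absorb compact letter display: two means
#' share a letter if and only if they are not significantly different at the
#' family-wise level `alpha`.
#'
#' @param group_means data.frame with `group`, `mean`, `n`.
#' @param ms_error within-groups (error) mean square from the ANOVA.
#' @param df_error its degrees of freedom.
#' @param alpha family-wise significance level (default 0.05).
#' @return `group_means` ordered by decreasing mean with a `letters` column.
#' @export
tukey_letters <- function(group_means, ms_error, df_error, alpha = 0.05) {
  stopifnot(all(c("group", "mean", "n") %in% names(group_means)),
            ms_error >= 0, df_error >= 1)
  g <- group_means[order(-group_means$mean), ]
  k <- nrow(g)
  if (k == 1L) {
    g$letters <- "A"
    rownames(g) <- NULL
    return(g)
  }
  # significance matrix from the studentized range distribution
  sig <- matrix(FALSE, k, k)
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      se <- sqrt(ms_error / 2 * (1 / g$n[i] + 1 / g$n[j]))
      p <- if (se == 0) {
        if (abs(g$mean[i] - g$mean[j]) < 1e-12) 1 else 0
      } else {
        q <- abs(g$mean[i] - g$mean[j]) / se
        stats::ptukey(q, nmeans = k, df = df_error, lower.tail = FALSE)
      }
      sig[i, j] <- sig[j, i] <- p < alpha
    }
  }
  cols <- list(seq_len(k))   # insert-and-absorb (Piepho 2004)
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      if (!sig[i, j]) next
      hit <- which(vapply(cols, function(cl) i %in% cl && j %in% cl, logical(1)))
      for (h in hit) {
        cl <- cols[[h]]
        cols[[h]] <- setdiff(cl, i)
        cols[[length(cols) + 1L]] <- setdiff(cl, j)
      }
      # absorb: drop columns contained in another column
      keep <- rep(TRUE, length(cols))
      for (x in seq_along(cols)) {
        for (y in seq_along(cols)) {
          if (x != y && keep[x] && keep[y] &&
              all(cols[[x]] %in% cols[[y]]) &&
              !(all(cols[[y]] %in% cols[[x]]) && x < y)) {
            keep[x] <- FALSE
          }
        }
      }
      cols <- cols[keep]
    }
  }
  # order letter columns by their best (highest) mean, then assign A, B, ...
  first <- vapply(cols, min, numeric(1))
  cols <- cols[order(first)]
  lab <- make_letters(length(cols))
  g$letters <- vapply(seq_len(k), function(i) {
    paste0(lab[vapply(cols, function(cl) i %in% cl, logical(1))], collapse = "")
  }, character(1))
  rownames(g) <- NULL
  g
}

make_letters <- function(n) {
  if (n <= 26) return(LETTERS[seq_len(n)])
  c(LETTERS, as.vector(outer(LETTERS, LETTERS, paste0)))[seq_len(n)]
}
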