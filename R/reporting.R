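#' Congruency grouping of audiovisual trials
#'
#' In the 9 x 9 audiovisual pairing matrix, congruent cells are the
#' diagonal (equal visual and auditory temporal frequency), anti-congruent
#' cells are the anti-diagonal (the auditory frequency mirrors the visual
#' one around the centre of the grid), and all remaining off-diagonal
#' cells are incongruent.
#'
#' @param visual_tf,sound_tf Paired frequency vectors in Hz.
#' @return Character vector: "congruent", "incongruent", "anti_congruent".
#' @export
congruency_of <- function(visual_tf, sound_tf) {
  tfs <- task_frequencies()
  vi <- match(visual_tf, tfs)
  ai <- match(sound_tf, tfs)
  out <- rep("incongruent", length(vi))
  out[vi == ai] <- "congruent"
  out[vi + ai == length(tfs) + 1 & vi != ai] <- "anti_congruent"
  out
}

#' Per-animal psychometric summary table
#'
#' Aggregates a trial table into per-animal, per-condition-group,
#' per-stimulus proportions of "high" reports.  Grouping
#' \code{"by_congruency"} labels trials as fixed / congruent /
#' incongruent / anti-congruent / visual-only; \code{"by_intensity_level"}
#' groups by the 5 perceived-intensity levels.  Auditory-only trials are
#' excluded (they carry no visual stimulus).
#'
#' @param trials Trial data frame.
#' @param grouping One of \code{"by_congruency"}, \code{"by_intensity_level"}.
#' @return Data frame with columns \code{rat_id}, \code{condition_group},
#'   \code{visual_tf}, \code{n_trials}, \code{prop_high}.
#' @export
psychometric_table <- function(trials,
                               grouping = c("by_congruency",
                                            "by_intensity_level")) {
  grouping <- match.arg(grouping)
  if (!nrow(trials)) stop("'trials' is empty")
  tr <- trials[!is.na(trials$visual_tf_hz), , drop = FALSE]
  grp <- if (grouping == "by_intensity_level") {
    paste0("level", tr$intensity_level)
  } else {
    g <- rep("v_only", nrow(tr))
    g[tr$sound_kind == "fixed"] <- "fixed"
    am <- tr$sound_kind == "am"
    g[am] <- congruency_of(tr$visual_tf_hz[am], tr$sound_tf_hz[am])
    g
  }
  key <- list(rat_id = tr$rat_id, condition_group = grp,
              visual_tf = tr$visual_tf_hz)
  agg_n <- aggregate(tr$choice, key, length)
  agg_p <- aggregate(tr$choice == "H", key, mean)
  out <- agg_n
  names(out)[4] <- "n_trials"
  out$prop_high <- agg_p$x
  out[order(out$rat_id, out$condition_group, out$visual_tf), ]
}

#' Arcsine square-root transform of proportions
#'
#' Variance-stabilising transform for choice proportions ahead of ANOVA:
#' \eqn{\arcsin\sqrt{p}}, mapping [0, 1] to [0, pi/2].
#'
#' @param p Proportions in [0, 1].
#' @return Transformed values.
#' @export
arcsine_transform <- function(p) {
  if (any(p < 0 | p > 1)) stop("'p' must lie in [0, 1]")
  asin(sqrt(p))
}

# Greenhouse-Geisser epsilon for a within-subject effect, from the
# per-subject cell-mean matrix and an orthonormal contrast matrix C
gg_epsilon <- function(M, C) {
  S <- cov(M)
  Sc <- C %*% S %*% t(C)
  d <- nrow(Sc)
  (sum(diag(Sc)))^2 / (d * sum(Sc^2))
}

#' Repeated-measures ANOVA on arcsine-transformed choice proportions
#'
#' Group-level frequentist check: arcsine-transforms the per-animal
#' proportions, tests normality per cell (Shapiro-Wilk) and
#' homoscedasticity across conditions (Levene), then runs a two-way
#' repeated-measures ANOVA with factors visual temporal frequency and
#' experimental condition, followed by Tukey pairwise comparisons of the
#' conditions.  Greenhouse-Geisser-corrected p-values are reported next
#' to the uncorrected ones.
#'
#' @param table Output of \code{\link{psychometric_table}}.
#' @param conditions Condition groups to include (must form a balanced
#'   animal x condition x frequency design).
#' @return A list with components \code{assumptions} (Shapiro and Levene
#'   results), \code{anova} (df, SS, MS, F, p, p_gg per effect) and
#'   \code{tukey} (pairwise condition contrasts on transformed and raw
#'   scales).
#' @export
group_anova <- function(table, conditions) {
  d <- table[table$condition_group %in% conditions, , drop = FALSE]
  d$y <- arcsine_transform(d$prop_high)
  d$rat <- factor(d$rat_id)
  d$cond <- factor(d$condition_group, levels = conditions)
  d$tf <- factor(d$visual_tf)
  cnt <- table(d$rat, d$cond, d$tf)
  if (any(cnt != 1)) {
    miss <- which(cnt != 1, arr.ind = TRUE)
    stop("unbalanced design; first problem cell: rat=",
         dimnames(cnt)[[1]][miss[1, 1]], " cond=",
         dimnames(cnt)[[2]][miss[1, 2]], " tf=", dimnames(cnt)[[3]][miss[1, 3]])
  }
  # assumption checks
  shapiro <- do.call(rbind, lapply(split(d, list(d$cond, d$tf)), function(cell) {
    s <- tryCatch(shapiro.test(cell$y), error = function(e) NULL)
    data.frame(cond = cell$cond[1], tf = cell$tf[1],
               W = if (is.null(s)) NA else unname(s$statistic),
               p = if (is.null(s)) NA else s$p.value)
  }))
  rownames(shapiro) <- NULL
  levene <- if (requireNamespace("car", quietly = TRUE)) {
    lv <- car::leveneTest(y ~ cond, data = d)
    data.frame(F = lv$`F value`[1], p = lv$`Pr(>F)`[1])
  } else {
    grp_med <- ave(d$y, d$cond, FUN = median)
    z <- abs(d$y - grp_med)
    a <- anova(lm(z ~ d$cond))
    data.frame(F = a$`F value`[1], p = a$`Pr(>F)`[1])
  }
  # repeated-measures ANOVA, both factors within-subject (data embedded in
  # the call so post-hoc machinery can re-fit outside this scope)
  fit <- do.call(aov, list(y ~ tf * cond + Error(rat / (tf * cond)), data = d))
  sm <- summary(fit)
  pull <- function(stratum, effect) {
    tab <- sm[[stratum]][[1]]
    i <- grep(effect, trimws(rownames(tab)), fixed = TRUE)[1]
    e <- tab[i, ]; r <- tab[nrow(tab), ]   # effect row + residual row
    data.frame(effect = effect, df = e$Df, SS = e$`Sum Sq`, MS = e$`Mean Sq`,
               F = e$`F value`, p = e$`Pr(>F)`,
               df_res = r$Df, SS_res = r$`Sum Sq`)
  }
  av <- rbind(pull("Error: rat:tf", "tf"),
              pull("Error: rat:cond", "cond"),
              pull("Error: rat:tf:cond", "tf:cond"))
  # Greenhouse-Geisser corrections from per-animal cell means
  wide_of <- function(fac) {
    M <- tapply(d$y, list(d$rat, fac), mean)
    M
  }
  eps <- c(
    tf = gg_eps_from_means(wide_of(d$tf)),
    cond = gg_eps_from_means(wide_of(d$cond)),
    `tf:cond` = gg_eps_from_means(tapply(d$y, list(d$rat,
                                                   interaction(d$tf, d$cond)),
                                         mean), int = c(nlevels(d$tf),
                                                        nlevels(d$cond))))
  av$gg_epsilon <- pmin(pmax(eps, 1 / av$df), 1)
  av$p_gg <- pf(av$F, av$df * av$gg_epsilon, av$df_res * av$gg_epsilon,
                lower.tail = FALSE)
  # Tukey pairwise comparisons of conditions
  tukey <- if (requireNamespace("emmeans", quietly = TRUE)) {
    em <- suppressMessages(emmeans::emmeans(fit, ~ cond, data = d))
    as.data.frame(suppressMessages(pairs(em, adjust = "tukey")))
  } else {
    as.data.frame(TukeyHSD(aov(y ~ tf + cond + rat, data = d), "cond")$cond)
  }
  raw <- aggregate(d$prop_high, list(cond = d$cond), mean)
  list(assumptions = list(shapiro = shapiro, levene = levene),
       anova = av, tukey = tukey, condition_means_raw = raw)
}

# GG epsilon; for interactions, uses the Kronecker product of the two
# factors' orthonormal contrast matrices
gg_eps_from_means <- function(M, int = NULL) {
  k <- ncol(M)
  Cm <- function(kk) {
    Q <- qr.Q(qr(contr.helmert(kk)))
    t(Q)
  }
  C <- if (is.null(int)) Cm(k) else kronecker(Cm(int[2]), Cm(int[1]))
  tryCatch(gg_epsilon(M, C), error = function(e) NA_real_)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' simulate -> intensity-level assignment -> model fit(s) -> comparison ->
#' report, with a manifest recording seeds and data digests.  The
#' configuration is a nested list (or a YAML file path) with sections
#' \code{cohort}, \code{model} (character vector of menu names),
#' \code{sampler} and \code{report}.
#'
#' @param config Nested list or path to a YAML file.
#' @param out_dir Optional directory for delimited-text outputs.
#' @return A list with the trial table, fits, comparison, report and
#'   manifest.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    config <- yaml::read_yaml(config)
  }
  cfg <- modifyList(list(
    seed = 1L,
    cohort = list(n_rats = 4, trials_per_rat = 400),
    model = "1s5g",
    sampler = list(chains = 2, adapt = 300, burn = 300, draws = 400),
    report = list(grouping = "by_intensity_level")), config)
  if ("linear" %in% cfg$model &&
      is.null(cfg$sampler$intensity_values) && is.null(cfg$intensity_values)) {
    if (!isTRUE(cfg$allow_default_intensities)) {
      stop("config error: the linear gain model requires 'intensity_values' ",
           "(per-level mean dB), or set allow_default_intensities: true")
    }
  }
  log <- character()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log <<- c(log, sprintf("%s: ok (%.1fs)", name,
                           as.numeric(Sys.time() - t0, units = "secs")))
    res
  }
  spec <- stage("simulate", do.call(cohort_spec,
                                    c(cfg$cohort, list(seed = cfg$seed))))
  trials <- stage("cohort", simulate_cohort(spec))
  stage("intensity", {
    lev <- intensity_level_of(trials$sound_kind, trials$sound_tf_hz)
    stopifnot(all(lev[trials$sound_kind != "am" | !is.na(trials$visual_tf_hz)] >= 1))
    invisible(lev)
  })
  fits <- stage("fit", {
    sampler <- cfg$sampler
    setNames(lapply(cfg$model, function(m) {
      ms <- if (m == "linear" && !is.null(cfg$intensity_values)) {
        model_spec("linear", intensity_values = cfg$intensity_values)
      } else m
      fit_observer(trials, model = ms, chains = sampler$chains,
                   adapt = sampler$adapt, burn = sampler$burn,
                   draws = sampler$draws, seed = cfg$seed)
    }), cfg$model)
  })
  comparison <- if (length(fits) > 1) {
    stage("compare", compare_models(lapply(fits, pointwise_elpd)))
  } else NULL
  report <- stage("report", psychometric_table(trials, cfg$report$grouping))
  manifest <- list(seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("soundgain")),
                   models = cfg$model,
                   n_trials = nrow(trials),
                   trial_digest = trial_digest(trials),
                   stages = log,
                   timestamp = format(Sys.time(), tz = "UTC"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_trials(trials, file.path(out_dir, "trials.tsv"))
    write.table(report, file.path(out_dir, "psychometric_table.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(comparison)) {
      write.table(as.data.frame(comparison),
                  file.path(out_dir, "model_comparison.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    }
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
    }
  }
  list(trials = trials, fits = fits, comparison = comparison,
       report = report, manifest = manifest)
}
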