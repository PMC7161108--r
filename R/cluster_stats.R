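#' Per-patient mutational burden of a pathway
#'
#' Fraction of the pathway's genes (restricted to genes covered by the
#' mutation table) that carry any somatic mutation in each patient.
#'
#' @param mutations Patients-by-genes binary (0/1) matrix with dimnames.
#' @param genes Character vector of the pathway's gene ids.
#' @return Named numeric vector of burdens in `[0, 1]`, or `NULL` (with a
#'   warning) when no pathway gene is covered by the table.
#' @export
mutational_burden <- function(mutations, genes) {
  mutations <- as.matrix(mutations)
  if (!all(mutations %in% c(0, 1))) {
    stop_input("mutation table must be binary (0/1)")
  }
  covered <- intersect(genes, colnames(mutations))
  if (length(covered) == 0L) {
    warn("no pathway gene covered by the mutation table; pathway skipped")
    return(NULL)
  }
  rowMeans(mutations[, covered, drop = FALSE])
}

#' Mutational-burden differences across clusters
#'
#' For each pathway, computes per-patient mutational burden and tests for
#' differences across clusters with a Kruskal-Wallis test; p-values are
#' Benjamini-Hochberg adjusted across all tested pathways (one family).
#'
#' @param mutations Patients-by-genes binary matrix.
#' @param gene_sets Named list of gene id vectors (e.g. [load_gene_sets()]).
#' @param labels Named cluster labels covering the mutation table patients.
#' @return Tibble with `pathway_id`, `n_genes_covered`, `statistic`,
#'   `p_value`, `p_adjusted`; the per-patient burden matrix is attached as
#'   the `"burden"` attribute.
#' @export
mutational_burden_test <- function(mutations, gene_sets, labels) {
  mutations <- as.matrix(mutations)
  patients <- intersect(rownames(mutations), names(labels))
  if (length(patients) == 0L) stop_input("no shared patients between mutations and labels")
  mutations <- mutations[patients, , drop = FALSE]
  lab <- factor(labels[patients])
  if (nlevels(lab) < 2L) stop_input("need at least 2 clusters")

  rows <- list()
  burdens <- list()
  for (pw in names(gene_sets)) {
    b <- mutational_burden(mutations, gene_sets[[pw]])
    if (is.null(b)) next
    kw <- kruskal.test(b, lab)
    burdens[[pw]] <- b
    rows[[pw]] <- tibble(
      pathway_id = pw,
      n_genes_covered = length(intersect(gene_sets[[pw]], colnames(mutations))),
      statistic = unname(kw$statistic),
      p_value = kw$p.value
    )
  }
  if (length(rows) == 0L) stop_input("no pathway overlaps the mutation table")
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  attr(out, "burden") <- do.call(rbind, burdens)
  out
}

#' Survival association of a clustering
#'
#' First fits an age-only Cox proportional-hazards model. If age is
#' nominally significant (p < `age_threshold`), the cluster association is
#' assessed by a likelihood-ratio test of `{cluster + age}` against the
#' age-only null (age-corrected branch); otherwise a conventional log-rank
#' test across clusters is used. The branch taken is recorded in `method`.
#'
#' @param labels Named cluster labels.
#' @param clinical Data frame with a `patient_id` column, an `age` column,
#'   and `<endpoint>_time` / `<endpoint>_event` columns.
#' @param endpoint One of `"os"`, `"pfs"`, `"dfs"` (or any prefix present
#'   in `clinical`).
#' @param age_threshold Nominal significance level for the age branch
#'   (default 0.05).
#' @return Tibble with `endpoint`, `method` (`"logrank"` or
#'   `"cox_lrt_age_adjusted"`), `p_value`, `age_p_value`, `n`.
#' @export
survival_association <- function(labels, clinical, endpoint = "os",
                                 age_threshold = 0.05) {
  tcol <- paste0(endpoint, "_time")
  ecol <- paste0(endpoint, "_event")
  if (!all(c(tcol, ecol, "age", "patient_id") %in% names(clinical))) {
    stop_input("clinical table lacks columns %s, %s, age or patient_id", tcol, ecol)
  }
  df <- clinical[match(names(labels), clinical$patient_id), ]
  df$cluster <- factor(labels)
  df <- df[complete.cases(df[, c(tcol, ecol, "age")]), ]
  if (nlevels(droplevels(df$cluster)) < 2L) stop_input("need at least 2 clusters")
  if (all(df[[ecol]] == 0)) {
    warn(sprintf("endpoint %s is fully censored; association undefined", endpoint))
    return(tibble(endpoint = endpoint, method = "undefined",
                  p_value = NA_real_, age_p_value = NA_real_, n = nrow(df)))
  }
  surv <- survival::Surv(df[[tcol]], df[[ecol]])

  age_fit <- survival::coxph(surv ~ age, data = df)
  age_p <- summary(age_fit)$coefficients["age", "Pr(>|z|)"]

  if (is.finite(age_p) && age_p < age_threshold) {
    full <- survival::coxph(surv ~ cluster + age, data = df)
    lrt <- 2 * (full$loglik[2] - age_fit$loglik[2])
    p <- pchisq(lrt, df = nlevels(droplevels(df$cluster)) - 1L, lower.tail = FALSE)
    method <- "cox_lrt_age_adjusted"
  } else {
    sd_fit <- survival::survdiff(surv ~ cluster, data = df)
    p <- pchisq(sd_fit$chisq, df = length(sd_fit$n) - 1L, lower.tail = FALSE)
    method <- "logrank"
  }
  tibble(endpoint = endpoint, method = method, p_value = p,
         age_p_value = age_p, n = nrow(df))
}

#' Clinical-variable associations of a clustering
#'
#' Tests every clinical covariate against the cluster labels: chi-square
#' for categorical variables (levels carried by a single patient are
#' pooled into `"other"` with a warning), one-way ANOVA for numeric ones.
#' P-values are BH-adjusted across the whole table (one family).
#' Survival endpoint columns and `patient_id` are skipped.
#'
#' @inheritParams survival_association
#' @param variables Optional character vector restricting the covariates.
#' @return Tibble with `variable`, `test`, `p_value`, `p_adjusted`.
#' @export
clinical_associations <- function(labels, clinical, variables = NULL) {
  df <- clinical[match(names(labels), clinical$patient_id), ]
  lab <- factor(labels)
  if (nlevels(lab) < 2L) stop_input("need at least 2 clusters")
  skip <- c("patient_id",
            grep("_(time|event)$", names(df), value = TRUE))
  vars <- setdiff(names(df), skip)
  if (!is.null(variables)) vars <- intersect(vars, variables)
  rows <- list()
  for (v in vars) {
    x <- df[[v]]
    keep <- !is.na(x)
    if (sum(keep) < 3L) next
    if (is.character(x) || is.factor(x) || is.logical(x)) {
      x <- factor(as.character(x[keep]))
      singletons <- names(which(table(x) <= 1L))
      if (length(singletons) > 0L) {
        warn(sprintf("variable %s: pooling %d singleton level(s) into 'other'",
                     v, length(singletons)))
        lv <- as.character(x)
        lv[lv %in% singletons] <- "other"
        x <- factor(lv)
      }
      if (nlevels(x) < 2L) next
      p <- suppressWarnings(chisq.test(table(x, lab[keep]))$p.value)
      test <- "chisq"
    } else {
      fit <- aov(x[keep] ~ lab[keep])
      p <- summary(fit)[[1]][["Pr(>F)"]][1]
      test <- "anova"
    }
    rows[[v]] <- tibble(variable = v, test = test, p_value = p)
  }
  if (length(rows) == 0L) stop_input("no testable clinical variables")
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  out
}
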