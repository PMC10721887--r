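# Phecode mapping, per-phecode logistic models, and phenome-wide
# fixed-effects meta-analysis.

#' Synthetic phecode map
#'
#' A compact phecode grouping shipped for simulation and tests: each phecode
#' carries its ICD-9 member codes, an exclusion range (phecode interval whose
#' members disqualify a participant from the control group), and a body
#' system group. Users may substitute the standard phecode map in the same
#' long format.
#'
#' @return data.frame: phecode, phecode_label, group, icd9, exclusion_range
#' @export
synthetic_phecode_map <- function() {
  def <- list(
    list(585.3, "Chronic kidney disease", "genitourinary",
         c("585.3", "585.9", "586"), "580-599.99"),
    list(599.7, "Hematuria", "genitourinary", "599.7", "580-599.99"),
    list(753.1, "Cystic kidney disease", "congenital",
         c("753.1", "753.13"), "753-753.99"),
    list(250.2, "Type 2 diabetes", "endocrine",
         c("250.00", "250.01"), "249-250.99"),
    list(401.1, "Essential hypertension", "circulatory",
         c("401.1", "401.9"), "401-405.99"),
    list(272.1, "Hyperlipidemia", "endocrine", c("272.0", "272.4"),
         "272-272.99"),
    list(296.2, "Depression", "mental", c("296.2", "311"), "296-296.99"),
    list(495, "Asthma", "respiratory", c("493.0", "493.9"), "490-496.99"),
    list(714.1, "Rheumatoid arthritis", "musculoskeletal", "714.0",
         "714-714.99"),
    list(530.1, "Esophagitis and GERD", "digestive", c("530.11", "530.81"),
         "530-530.99"),
    list(340, "Migraine", "neurological", c("346.0", "346.9"), "340-346.99"),
    list(365, "Glaucoma", "sense organs", "365.9", "365-365.99"),
    list(550.1, "Inguinal hernia", "digestive", "550.9", "550-553.99"),
    list(610, "Benign breast condition", "genitourinary", "610.1",
         "610-611.99"),
    list(300.1, "Anxiety disorder", "mental", "300.00", "300-300.99"),
    list(455, "Hemorrhoids", "circulatory", "455.6", "455-455.99"))
  do.call(rbind, lapply(def, function(d) {
    data.frame(phecode = d[[1]], phecode_label = d[[2]], group = d[[3]],
               icd9 = d[[4]], exclusion_range = d[[5]],
               stringsAsFactors = FALSE)
  }))
}

parse_range <- function(x) {
  parts <- strsplit(x, "-", fixed = TRUE)[[1]]
  as.numeric(parts[1:2])
}

#' Map ICD code multisets to phecode case/control status
#'
#' A participant is a case for a phecode with two or more occurrences of
#' codes mapping into that phecode (occurrences are counted as code
#' instances), a control with zero occurrences of any code mapping into the
#' phecode's exclusion range, and missing otherwise (including the
#' single-occurrence zone). Unmapped codes are counted and reported via a
#' message, never dropped silently.
#'
#' @param icd9_codes character vector, one semicolon-separated multiset per
#'   participant
#' @param map phecode map (see [synthetic_phecode_map()])
#' @return list: `status` (participants x phecodes matrix of 1/0/NA),
#'   `counts` (occurrence counts), `unmapped` (count of unmapped code
#'   instances), `map` (per-phecode metadata)
#' @export
map_codes <- function(icd9_codes, map) {
  phe <- sort(unique(map$phecode))
  code_list <- strsplit(ifelse(is.na(icd9_codes), "", icd9_codes), ";",
                        fixed = TRUE)
  n <- length(code_list)
  counts <- matrix(0L, n, length(phe),
                   dimnames = list(NULL, as.character(phe)))
  unmapped <- 0L
  code2phe <- split(map$phecode, map$icd9)
  for (i in seq_len(n)) {
    cc <- code_list[[i]]
    cc <- cc[nzchar(cc)]
    if (length(cc) == 0) next
    hit <- code2phe[cc]
    miss <- vapply(hit, is.null, logical(1))
    unmapped <- unmapped + sum(miss)
    for (ph in unlist(hit[!miss]))
      counts[i, as.character(ph)] <- counts[i, as.character(ph)] + 1L
  }
  if (unmapped > 0)
    message(unmapped, " ICD code occurrence(s) did not map to any phecode")
  meta <- unique(map[, c("phecode", "phecode_label", "group",
                         "exclusion_range")])
  meta <- meta[order(meta$phecode), , drop = FALSE]
  status <- matrix(NA_real_, n, length(phe),
                   dimnames = list(NULL, as.character(phe)))
  for (j in seq_along(phe)) {
    rng <- parse_range(meta$exclusion_range[j])
    in_range <- phe >= rng[1] & phe <= rng[2]
    control <- rowSums(counts[, in_range, drop = FALSE]) == 0
    status[control, j] <- 0
    status[counts[, j] >= 2L, j] <- 1
  }
  list(status = status, counts = counts, unmapped = unmapped, map = meta)
}

#' Per-phecode carrier association scan
#'
#' Logistic regression of each phecode's case/control status on dominant
#' carrier status, adjusted by default for sex, age, batch, and five ancestry
#' PCs. Phecodes with fewer than `min_cases` cases are skipped with a reason;
#' non-convergent fits are flagged and excluded from meta-analysis.
#'
#' @param phecode_status status matrix from [map_codes()]
#' @param carrier logical carrier indicator per participant
#' @param covariate_data data.frame of covariates aligned with participants
#' @param covariates covariate columns to adjust for
#' @param min_cases minimum case count per phecode (default 20)
#' @param cohort label recorded in the output
#' @return data.frame, one row per phecode: beta, se, p, n_cases, status
#' @export
run_phewas <- function(phecode_status, carrier, covariate_data,
                       covariates = default_covariates(n_pcs = 5,
                                                       diabetes = FALSE),
                       min_cases = 20, cohort = "cohort") {
  phe <- colnames(phecode_status)
  rows <- lapply(phe, function(ph) {
    st <- phecode_status[, ph]
    use <- !is.na(st)
    base <- data.frame(phecode = as.numeric(ph), cohort = cohort,
                       beta = NA_real_, se = NA_real_, p = NA_real_,
                       n_cases = sum(st == 1, na.rm = TRUE),
                       n_controls = sum(st == 0, na.rm = TRUE),
                       status = "ok", stringsAsFactors = FALSE)
    if (base$n_cases < min_cases) {
      base$status <- "skipped_min_cases"; return(base)
    }
    d <- covariate_data[use, , drop = FALSE]
    d$case <- st[use]
    d$carrier <- carrier[use]
    if (length(unique(d$carrier)) < 2) {
      base$status <- "skipped_no_carriers"; return(base)
    }
    f <- covariate_formula("case ~ carrier", covariates, d)
    tab <- tryCatch(suppressWarnings(fit_logistic(f, d)),
                    error = function(e) NULL)
    r <- if (is.null(tab)) NULL else tab[tab$term == "carrierTRUE", ]
    if (is.null(r) || nrow(r) == 0 || !is.finite(r$se)) {
      base$status <- "non_convergent"; return(base)
    }
    base$beta <- r$estimate; base$se <- r$se; base$p <- r$p
    base
  })
  do.call(rbind, rows)
}

#' Bonferroni phenome-wide significance threshold
#'
#' 0.05 divided by the number of phecodes tested.
#' @param n_phecodes number of phecodes tested
#' @export
phewas_threshold <- function(n_phecodes) 0.05 / n_phecodes

#' Fixed-effects meta-analysis across cohorts, phenome-wide
#'
#' Pools per-phecode estimates with [meta_fixed()]; phecodes flagged
#' non-convergent or skipped in a cohort contribute nothing from that
#' cohort. The significance threshold is 0.05 divided by the number of
#' phecodes with at least one usable cohort estimate. Output is ordered by
#' system group then phecode for stable Manhattan-style plotting.
#'
#' @param results list of per-cohort data.frames from [run_phewas()]
#' @param map phecode metadata (from [map_codes()] or the map itself)
#' @return list: `results` data.frame with meta OR/CI/p, direction, and
#'   `significant` flag; `threshold`
#' @export
meta_phewas <- function(results, map = NULL) {
  all_res <- do.call(rbind, results)
  usable <- all_res[all_res$status == "ok" & is.finite(all_res$se), ,
                    drop = FALSE]
  phe <- sort(unique(usable$phecode))
  n_tested <- length(phe)
  thr <- phewas_threshold(n_tested)
  rows <- lapply(phe, function(ph) {
    sub <- usable[usable$phecode == ph, , drop = FALSE]
    m <- meta_fixed(sub$beta, sub$se, sub$cohort)
    data.frame(phecode = ph, or = m$or, ci_lower = m$ci_lower,
               ci_upper = m$ci_upper, p = m$p,
               direction = ifelse(m$logOR >= 0, "up", "down"),
               n_cases = sum(sub$n_cases), k_cohorts = m$k,
               significant = m$p < thr, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(map)) {
    meta <- unique(map[, intersect(c("phecode", "phecode_label", "group"),
                                   names(map))])
    out <- merge(out, meta, by = "phecode", all.x = TRUE, sort = FALSE)
    out <- out[order(out$group, out$phecode), , drop = FALSE]
  }
  rownames(out) <- NULL
  list(results = out, threshold = thr, n_phecodes_tested = n_tested)
}
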