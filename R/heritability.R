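#' Intraclass correlation for exchangeable pairs
#'
#' One-way random-effects ANOVA intraclass correlation for pairs (k = 2
#' exchangeable members): `(MS_between - MS_within) / (MS_between +
#' MS_within)`. Because neither twin of a pair has a natural order, the
#' ICC -- not an ordered Pearson correlation -- is the standard measure of
#' intra-pair resemblance; it is invariant to swapping members within any
#' pair, and bounded in `[-1, 1]`.
#'
#' @param yA,yB numeric, the two members' phenotypes, one entry per pair;
#'   at least 3 pairs, finite values.
#' @return The ICC.
#' @examples
#' intraclassCorrelation(c(1, 2, 3), c(1, 2, 3))  # 1
#' @export
intraclassCorrelation <- function(yA, yB) {
  .checkPairs(yA, yB)
  n <- length(yA)
  mWithin <- sum((yA - yB)^2 / 2) / n            # MS within, df = n
  pairMeans <- (yA + yB) / 2
  mBetween <- 2 * sum((pairMeans - mean(pairMeans))^2) / (n - 1)
  if (mBetween + mWithin == 0)
    .domainError("ICC undefined: zero total variance across pairs")
  (mBetween - mWithin) / (mBetween + mWithin)
}

#' Pearson correlation on double-entered pairs
#'
#' Enters every pair twice, as (a, b) and (b, a), and takes the ordinary
#' Pearson correlation of the doubled list. Symmetric by construction and
#' asymptotically equal to the ANOVA ICC (they differ by O(1/n) on any
#' fixed dataset).
#'
#' @inheritParams intraclassCorrelation
#' @return The double-entry Pearson correlation.
#' @export
pearsonDoubleEntry <- function(yA, yB) {
  .checkPairs(yA, yB)
  u <- c(yA, yB); v <- c(yB, yA)
  if (var(u) == 0)
    .domainError("double-entry correlation undefined: zero variance")
  cor(u, v)
}

.checkPairs <- function(yA, yB) {
  if (length(yA) != length(yB))
    .domainError("the two member vectors must have equal length")
  if (length(yA) < 3L)
    .domainError("need >= 3 pairs (got %d)", length(yA))
  if (any(!is.finite(yA)) || any(!is.finite(yB)))
    .domainError("pair phenotypes must be finite")
  invisible(NULL)
}

#' Falconer's heritability estimate
#'
#' `h2 = 2 * (r_MZ - r_DZ)`: twice the excess resemblance of monozygotic
#' twins (who share all additive genetic variance) over dizygotic-like
#' pairs (full siblings, who share half). The raw value is returned even
#' when it falls outside `[0, 1]` -- sampling error can produce such
#' estimates and silently clipping them biases downstream summaries; set
#' `truncate = TRUE` to clip to `[0, 1]` explicitly.
#'
#' @param rMZ,rSIB intra-pair correlations in `[-1, 1]` for the
#'   monozygotic and sibling groups.
#' @param truncate clip the estimate to `[0, 1]`? Default `FALSE`.
#' @return Heritability as a fraction (0.70 means 70%).
#' @examples
#' falconerH2(0.60, 0.25)  # 0.70
#' @export
falconerH2 <- function(rMZ, rSIB, truncate = FALSE) {
  .assertScalarNumber(rMZ, "rMZ"); .assertScalarNumber(rSIB, "rSIB")
  if (abs(rMZ) > 1 || abs(rSIB) > 1)
    .domainError("correlations must lie in [-1, 1]")
  est <- 2 * (rMZ - rSIB)
  if (truncate) est <- min(max(est, 0), 1)
  est
}

# fast internal h2 for the permutation loop: no input re-validation
.h2Fast <- function(aMZ, bMZ, aSIB, bSIB, estimator) {
  if (estimator == "icc") {
    2 * (.iccFast(aMZ, bMZ) - .iccFast(aSIB, bSIB))
  } else {
    2 * (cor(c(aMZ, bMZ), c(bMZ, aMZ)) - cor(c(aSIB, bSIB), c(bSIB, aSIB)))
  }
}

.iccFast <- function(a, b) {
  n <- length(a)
  mW <- sum((a - b)^2 / 2) / n
  pm <- (a + b) / 2
  mB <- 2 * sum((pm - mean(pm))^2) / (n - 1)
  (mB - mW) / (mB + mW)
}

#' Permutation-based empirical p-value for heritability
#'
#' Computes the observed Falconer heritability, then builds a null
#' distribution by repeatedly destroying the pair structure and
#' recomputing the statistic. The default `"individual"` scheme pools all
#' `2 n_MZ + 2 n_SIB` phenotype values and randomly re-deals them into
#' pseudo-pairs preserving the group sizes; the alternative
#' `"pair_label"` scheme keeps pairs intact and permutes the zygosity
#' labels across pairs. The empirical p-value uses the add-one rule,
#' `p = (1 + #\{h2_null >= h2_obs\}) / (1 + n_perm)`, so it is never 0 and
#' never claims resolution beyond `1/(n_perm + 1)`.
#'
#' @param pairsDF data.frame with columns `zygosity` (`MZ`/`SIB`), `y_a`,
#'   `y_b` (one row per pair), e.g. from [simulatePairPhenotypes()].
#' @param nPerm number of permutations (study convention: 10000).
#' @param seed integer RNG seed (mandatory: results are reproducible
#'   bit-for-bit under the same seed).
#' @param estimator `"icc"` (ANOVA intraclass correlation, default) or
#'   `"double_entry"` (Pearson on double-entered pairs).
#' @param scheme `"individual"` (default) or `"pair_label"`.
#' @return A list: `p` (empirical p-value), `observedH2`, `nullH2`
#'   (numeric vector, length `nPerm`), `nullSummary` (mean, sd,
#'   quantiles), `nPerm`, `seed`, `estimator`, `scheme`.
#' @export
permutationPvalue <- function(pairsDF, nPerm = 10000L, seed,
                              estimator = c("icc", "double_entry"),
                              scheme = c("individual", "pair_label")) {
  estimator <- match.arg(estimator)
  scheme <- match.arg(scheme)
  nPerm <- as.integer(nPerm)
  if (is.na(nPerm) || nPerm < 1L) .domainError("nPerm must be >= 1")
  if (missing(seed)) .domainError("a seed is required for the permutation null")
  .requireColumns(pairsDF, c("zygosity", "y_a", "y_b"), "pair phenotype table")

  mz <- pairsDF[pairsDF$zygosity == "MZ", ]
  sib <- pairsDF[pairsDF$zygosity == "SIB", ]
  nMZ <- nrow(mz); nSIB <- nrow(sib)
  if (nMZ < 3L || nSIB < 3L)
    .domainError("need >= 3 pairs in each zygosity group (got %d MZ, %d SIB)",
                 nMZ, nSIB)
  # observed statistic with full validation (degenerate data errors here)
  rObsMZ <- if (estimator == "icc") intraclassCorrelation(mz$y_a, mz$y_b)
            else pearsonDoubleEntry(mz$y_a, mz$y_b)
  rObsSIB <- if (estimator == "icc") intraclassCorrelation(sib$y_a, sib$y_b)
             else pearsonDoubleEntry(sib$y_a, sib$y_b)
  obs <- falconerH2(rObsMZ, rObsSIB)

  set.seed(as.integer(seed))
  nullH2 <- numeric(nPerm)
  if (scheme == "individual") {
    # sorted pool: the re-dealt null is invariant to pair and member order
    pool <- sort(c(mz$y_a, mz$y_b, sib$y_a, sib$y_b))
    N <- length(pool)
    for (i in seq_len(nPerm)) {
      s <- pool[sample.int(N)]
      nullH2[i] <- .h2Fast(s[seq_len(nMZ)], s[nMZ + seq_len(nMZ)],
                           s[2 * nMZ + seq_len(nSIB)],
                           s[2 * nMZ + nSIB + seq_len(nSIB)], estimator)
    }
  } else {
    a <- c(mz$y_a, sib$y_a); b <- c(mz$y_b, sib$y_b)
    nP <- nMZ + nSIB
    for (i in seq_len(nPerm)) {
      idx <- sample.int(nP)
      mzIdx <- idx[seq_len(nMZ)]; sibIdx <- idx[nMZ + seq_len(nSIB)]
      nullH2[i] <- .h2Fast(a[mzIdx], b[mzIdx], a[sibIdx], b[sibIdx], estimator)
    }
  }
  p <- (1 + sum(nullH2 >= obs)) / (1 + nPerm)
  list(p = p, observedH2 = obs, nullH2 = nullH2,
       nullSummary = c(mean = mean(nullH2), sd = sd(nullH2),
                       quantile(nullH2, c(0.025, 0.25, 0.5, 0.75, 0.975))),
       nPerm = nPerm, seed = as.integer(seed),
       estimator = estimator, scheme = scheme)
}

#' Screen candidate confounders of the adhesion phenotype
#'
#' Per covariate, the appropriate bivariate test against the per-sample
#' phenotype: continuous covariates (age, transformation time) get a
#' Pearson correlation with its two-sided p-value; two-level covariates
#' (sex, growth class) a two-sample t-test; covariates with more than two
#' levels (ethnicity) a one-way ANOVA. Unadjusted p-values are reported
#' (matching standard single-covariate screening practice) alongside a
#' Bonferroni-adjusted column. Constant covariates are flagged
#' not-testable rather than forced.
#'
#' @param phenotype numeric, one value per sample.
#' @param covariates data.frame, one row per sample, one column per
#'   covariate; numeric columns are treated as continuous, others as
#'   categorical.
#' @return data.frame: `covariate, type, statistic, p, p_bonferroni, n,
#'   note`.
#' @export
confounderScreen <- function(phenotype, covariates) {
  phenotype <- as.numeric(phenotype)
  if (!is.data.frame(covariates) || nrow(covariates) != length(phenotype))
    .domainError("covariates must be a data.frame with one row per sample")
  rows <- lapply(names(covariates), function(nm) {
    v <- covariates[[nm]]
    ok <- is.finite(phenotype) & !is.na(v)
    y <- phenotype[ok]; x <- v[ok]
    n <- sum(ok)
    row <- data.frame(covariate = nm, type = NA_character_,
                      statistic = NA_real_, p = NA_real_,
                      n = n, note = "", stringsAsFactors = FALSE)
    if (n < 3L) { row$note <- "fewer than 3 samples with covariate"; return(row) }
    if (is.numeric(x)) {
      if (var(x) == 0) { row$type <- "continuous"; row$note <- "constant covariate: not testable"; return(row) }
      ct <- cor.test(y, x, method = "pearson")
      row$type <- "continuous"; row$statistic <- unname(ct$estimate)
      row$p <- ct$p.value
    } else {
      x <- factor(x)
      x <- droplevels(x)
      if (nlevels(x) < 2L) { row$type <- "categorical"; row$note <- "constant covariate: not testable"; return(row) }
      if (nlevels(x) == 2L) {
        if (any(table(x) < 2L)) { row$type <- "binary"; row$note <- "a level has < 2 samples"; return(row) }
        tt <- t.test(y ~ x)
        row$type <- "binary"; row$statistic <- unname(tt$statistic)
        row$p <- tt$p.value
      } else {
        av <- anova(lm(y ~ x))
        row$type <- "multi_level"; row$statistic <- av[["F value"]][1]
        row$p <- av[["Pr(>F)"]][1]
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  m <- sum(!is.na(out$p))
  out$p_bonferroni <- pmin(out$p * m, 1)
  out[, c("covariate", "type", "statistic", "p", "p_bonferroni", "n", "note")]
}

#' Equality of phenotype variance across groups
#'
#' Two-sided variance-ratio F-test (larger sample variance in the
#' numerator) between two groups of phenotype values -- e.g. testing
#' whether adhesion is equally variable across ethnicity groups. With more
#' than two groups, all pairwise tests are run with Bonferroni adjustment
#' and the result is flagged accordingly.
#'
#' @param values numeric phenotype values.
#' @param group a factor/character of group labels; each group needs
#'   `n >= 2` and non-zero variance.
#' @return A list: `p` (the p-value; for >2 groups the minimum
#'   Bonferroni-adjusted pairwise p), `statistic` (F, two-group case),
#'   `pairwise` (data.frame for >2 groups, else `NULL`), `note`.
#' @export
varianceEquality <- function(values, group) {
  values <- as.numeric(values)
  group <- factor(group)
  ok <- is.finite(values) & !is.na(group)
  values <- values[ok]; group <- droplevels(group[ok])
  if (nlevels(group) < 2L) .domainError("need >= 2 groups")
  if (any(table(group) < 2L)) .domainError("every group needs n >= 2")
  vs <- tapply(values, group, var)
  if (any(vs == 0)) .domainError("a group has zero variance; F-test undefined")
  vtest <- function(x1, x2) {
    # larger variance in the numerator so F >= 1 is reportable
    if (var(x1) < var(x2)) { tmp <- x1; x1 <- x2; x2 <- tmp }
    var.test(x1, x2)
  }
  if (nlevels(group) == 2L) {
    sp <- split(values, group)
    vt <- vtest(sp[[1]], sp[[2]])
    return(list(p = vt$p.value, statistic = unname(vt$statistic),
                pairwise = NULL, note = NA_character_))
  }
  combs <- utils::combn(levels(group), 2)
  rows <- apply(combs, 2, function(gg) {
    vt <- vtest(values[group == gg[1]], values[group == gg[2]])
    data.frame(group1 = gg[1], group2 = gg[2], F = unname(vt$statistic),
               p = vt$p.value, stringsAsFactors = FALSE)
  })
  pw <- do.call(rbind, rows)
  pw$p_bonferroni <- pmin(pw$p * nrow(pw), 1)
  list(p = min(pw$p_bonferroni), statistic = NA_real_, pairwise = pw,
       note = "more than 2 groups: pairwise F-tests with Bonferroni adjustment")
}

#' Run the full twin-design heritability analysis
#'
#' Joins per-sample phenotypes to the pair manifest, computes the
#' intra-pair correlation for each zygosity group with the configured
#' estimator, the Falconer heritability, and the permutation-based
#' empirical p-value, and returns everything with its provenance (seed,
#' estimator, scheme, phenotype scale, group sizes).
#'
#' @param phenotypes either a named numeric vector (one phenotype per
#'   sample id) or the data.frame from [quantifyAdhesion()].
#' @param manifest a [PairManifest-class].
#' @param phenotypeScale which column to use from a phenotype table:
#'   `"pct_input_rfu"` (default, the assay's primary readout) or
#'   `"pct_adherent"`.
#' @param estimator,scheme,nPerm,seed passed to [permutationPvalue()].
#' @param truncate clip h2 to `[0, 1]`? Default `FALSE`; out-of-range raw
#'   estimates are flagged in the result either way.
#' @param dropIncomplete if `TRUE`, pairs with a member lacking a (finite)
#'   phenotype -- e.g. samples whose only plate failed QC -- are dropped
#'   with a warning instead of raising an error. Default `FALSE`: unmatched
#'   sample ids are an error listing them.
#' @return A [HeritabilityResult-class].
#' @examples
#' cfg <- GenerativeConfig(seed = 7)
#' sim <- simulatePairPhenotypes(cfg)
#' pheno <- setNames(sim$samples$phenotype, sim$samples$sample_id)
#' runHeritabilityAnalysis(pheno, sim$manifest, nPerm = 200, seed = 7)
#' @export
runHeritabilityAnalysis <- function(phenotypes, manifest,
                                    phenotypeScale = c("pct_input_rfu",
                                                       "pct_adherent"),
                                    estimator = c("icc", "double_entry"),
                                    scheme = c("individual", "pair_label"),
                                    nPerm = 10000L, seed = 1L,
                                    truncate = FALSE, dropIncomplete = FALSE) {
  phenotypeScale <- match.arg(phenotypeScale)
  estimator <- match.arg(estimator)
  scheme <- match.arg(scheme)
  stopifnot(is(manifest, "PairManifest"))
  if (is.data.frame(phenotypes)) {
    col <- paste0(phenotypeScale, "_mean")
    .requireColumns(phenotypes, c("sample_id", col), "phenotype table")
    phenotypes <- setNames(phenotypes[[col]], phenotypes$sample_id)
  }
  pr <- manifest@pairs
  wanted <- c(pr$sample_id_a, pr$sample_id_b)
  missing <- wanted[!wanted %in% names(phenotypes)]
  if (length(missing) && !dropIncomplete)
    .domainError("no phenotype for paired sample(s): %s", .fmtSome(missing))
  pairsDF <- data.frame(pair_id = pr$pair_id, zygosity = pr$zygosity,
                        y_a = unname(phenotypes[pr$sample_id_a]),
                        y_b = unname(phenotypes[pr$sample_id_b]),
                        stringsAsFactors = FALSE)
  incomplete <- !is.finite(pairsDF$y_a) | !is.finite(pairsDF$y_b)
  if (any(incomplete)) {
    if (!dropIncomplete)
      .domainError("paired sample(s) have non-finite phenotypes")
    warning(sprintf("dropping %d pair(s) with unquantified members",
                    sum(incomplete)))
    pairsDF <- pairsDF[!incomplete, , drop = FALSE]
  }
  zt <- table(factor(pairsDF$zygosity, levels = c("MZ", "SIB")))
  if (any(zt < 2L))
    .domainError("need >= 2 pairs in each zygosity group (got %d MZ, %d SIB)",
                 zt[["MZ"]], zt[["SIB"]])
  perm <- permutationPvalue(pairsDF, nPerm = nPerm, seed = seed,
                            estimator = estimator, scheme = scheme)
  mz <- pairsDF[pairsDF$zygosity == "MZ", ]
  sib <- pairsDF[pairsDF$zygosity == "SIB", ]
  rmz <- if (estimator == "icc") intraclassCorrelation(mz$y_a, mz$y_b)
         else pearsonDoubleEntry(mz$y_a, mz$y_b)
  rsib <- if (estimator == "icc") intraclassCorrelation(sib$y_a, sib$y_b)
          else pearsonDoubleEntry(sib$y_a, sib$y_b)
  h2raw <- falconerH2(rmz, rsib)
  h2out <- h2raw < 0 || h2raw > 1
  new("HeritabilityResult",
      rMZ = rmz, rSIB = rsib,
      h2 = if (truncate) min(max(h2raw, 0), 1) else h2raw,
      h2OutOfRange = h2out,
      pEmpirical = perm$p, nPerm = perm$nPerm, nullH2 = perm$nullH2,
      nullSummary = perm$nullSummary, estimator = estimator, scheme = scheme,
      phenotypeScale = phenotypeScale, seed = as.integer(seed),
      nPairs = c(MZ = as.integer(zt[["MZ"]]), SIB = as.integer(zt[["SIB"]])))
}

#' Serialize a heritability result to JSON
#'
#' @param x a [HeritabilityResult-class].
#' @param path output path.
#' @param includeNull include the full permutation null vector? Default
#'   `FALSE` (the summary quantiles are always included).
#' @return `path`, invisibly.
#' @export
writeHeritabilityResult <- function(x, path, includeNull = FALSE) {
  stopifnot(is(x, "HeritabilityResult"))
  payload <- list(
    r_mz = x@rMZ, r_sib = x@rSIB, h2 = x@h2, h2_percent = 100 * x@h2,
    h2_out_of_range = x@h2OutOfRange,
    p_empirical = x@pEmpirical, n_perm = x@nPerm,
    null_summary = as.list(x@nullSummary),
    estimator = x@estimator, scheme = x@scheme,
    phenotype_scale = x@phenotypeScale, seed = x@seed,
    n_pairs = as.list(x@nPairs))
  if (includeNull) payload$null_h2 <- x@nullH2
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
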