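#' Read a genotype feature matrix from a dosage table or VCF
#'
#' The panel file is authoritative for which allele is counted: dosage is
#' the number of copies of the panel's \code{effect_allele} (0/1/2).  For a
#' VCF, records are matched to the panel by id; when the effect allele is
#' the ALT allele the ALT count is used directly, when it equals REF the
#' dosage is \code{2 - ALT count}, and any other combination is a hard
#' error naming the site.  Half-missing genotypes (e.g., \code{./1}) are
#' treated as missing.
#'
#' @param path Path to a tab-separated dosage table (first column
#'   \code{subject_id}) or a VCF 4.x file.
#' @param panel data.frame with at least \code{snp_id}, \code{ref},
#'   \code{alt}, \code{effect_allele} (required for VCF input; for dosage
#'   tables it selects/validates columns when supplied).
#' @param format \code{"auto"} (by extension), \code{"tsv"}, or
#'   \code{"vcf"}.
#' @param max_missing_subject,max_missing_snp Maximum tolerated missingness
#'   per subject / per SNP; offenders above threshold are an error listing
#'   them.
#' @return Numeric matrix subjects x features with a \code{feature_type}
#'   attribute.
#' @export
read_genotypes <- function(path, panel = NULL,
                           format = c("auto", "tsv", "vcf"),
                           max_missing_subject = 0.1,
                           max_missing_snp = 0.1) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  G <- if (format == "vcf") read_genotypes_vcf(path, panel)
  else read_genotypes_tsv(path, panel)
  check_missingness(G, max_missing_subject, max_missing_snp)
  G
}

read_genotypes_tsv <- function(path, panel) {
  d <- read_tsv_table(path)
  stopifnot("subject_id" %in% colnames(d))
  G <- as.matrix(d[, setdiff(colnames(d), "subject_id"), drop = FALSE])
  rownames(G) <- d$subject_id
  storage.mode(G) <- "double"
  if (!is.null(panel)) {
    missing <- setdiff(panel$snp_id, colnames(G))
    if (length(missing))
      stop("panel SNPs absent from dosage table: ",
           paste(missing, collapse = ", "))
  }
  attr(G, "feature_type") <- infer_feature_type(colnames(G), panel)
  G
}

read_genotypes_vcf <- function(path, panel) {
  if (is.null(panel)) stop("a SNP panel is required to read a VCF")
  if (anyDuplicated(panel$snp_id)) stop("panel SNP ids must be unique")
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("the vcfR package is required to read VCF input")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  idx <- match(panel$snp_id, fix$ID)
  if (anyNA(idx))
    stop("panel SNPs absent from VCF: ",
         paste(panel$snp_id[is.na(idx)], collapse = ", "))
  G <- matrix(NA_real_, ncol(gt), nrow(panel),
              dimnames = list(colnames(gt), panel$snp_id))
  for (j in seq_len(nrow(panel))) {
    i <- idx[j]
    ref <- fix$REF[i]; alt <- fix$ALT[i]
    ea <- panel$effect_allele[j]
    if (grepl(",", alt))
      stop("site ", panel$snp_id[j], " is not bi-allelic in the VCF")
    alt_count <- gt_to_alt_count(gt[i, ])
    if (ea == alt) {
      G[, j] <- alt_count
    } else if (ea == ref) {
      G[, j] <- 2 - alt_count
    } else {
      stop(sprintf(
        "site %s: effect allele %s matches neither REF (%s) nor ALT (%s)",
        panel$snp_id[j], ea, ref, alt))
    }
  }
  attr(G, "feature_type") <- rep("snp", ncol(G))
  G
}

# "0/1", "0|1" -> ALT allele count; any missing allele -> NA
gt_to_alt_count <- function(gt) {
  parts <- strsplit(gt, "[/|]")
  vapply(parts, function(p) {
    if (length(p) != 2 || any(p == ".") || any(is.na(p))) return(NA_real_)
    sum(p != "0")
  }, numeric(1))
}

infer_feature_type <- function(nms, panel = NULL) {
  snps <- if (!is.null(panel)) nms %in% panel$snp_id
  else !(nms %in% c("sex", "c9orf72", "other_mutation") |
           grepl("^PC[0-9]+$", nms))
  ifelse(snps, "snp",
         ifelse(grepl("^PC[0-9]+$", nms), "pc", "binary"))
}

check_missingness <- function(G, max_subj, max_snp) {
  fr_subj <- rowMeans(is.na(G))
  fr_snp <- colMeans(is.na(G))
  bad_s <- rownames(G)[fr_subj > max_subj]
  bad_m <- colnames(G)[fr_snp > max_snp]
  if (length(bad_s) || length(bad_m))
    stop("missingness above threshold for ",
         paste(c(sprintf("subject %s", bad_s),
                 sprintf("feature %s", bad_m)), collapse = ", "))
  invisible(G)
}

#' Write SNP dosages as a minimal VCF 4.2
#'
#' One record per panel SNP; dosages (counts of the effect allele) are
#' recoded to unphased genotypes.  Effect alleles equal to the panel's ALT
#' become ALT counts; effect alleles equal to REF are recoded accordingly.
#' Missing dosages become \code{./.}.
#'
#' @param dosages Subjects x SNPs matrix of 0/1/2 effect-allele counts.
#' @param panel Panel data.frame (\code{snp_id}, \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{effect_allele}).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_vcf <- function(dosages, panel, path) {
  stopifnot(all(colnames(dosages) == panel$snp_id))
  subjects <- rownames(dosages)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=sccaPRS-synthetic-cohort",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", subjects), collapse = "\t"))
  gt_code <- c("0/0", "0/1", "1/1")
  recs <- vapply(seq_len(nrow(panel)), function(j) {
    dos <- dosages[, j]
    alt_count <- if (panel$effect_allele[j] == panel$alt[j]) dos else 2 - dos
    gt <- ifelse(is.na(alt_count), "./.", gt_code[alt_count + 1])
    paste(c(panel$chrom[j], panel$pos[j], panel$snp_id[j], panel$ref[j],
            panel$alt[j], ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Principal components of a dosage matrix
#'
#' First \code{k} principal-component scores of the column-standardized
#' dosage matrix (missing values mean-imputed before standardization), for
#' use as population-structure adjustment features.  Sign convention: each
#' component is flipped, if needed, so that its largest-magnitude loading
#' is positive, making scores deterministic.
#'
#' @param dosages Subjects x SNPs numeric matrix.
#' @param k Number of components.
#' @return Subjects x k matrix with columns \code{PC1..PCk}.
#' @export
compute_pcs <- function(dosages, k = 2) {
  D <- as.matrix(dosages)
  if (nrow(D) < k + 1) stop("need at least k + 1 subjects")
  for (j in seq_len(ncol(D))) {
    mis <- is.na(D[, j])
    if (any(mis)) D[mis, j] <- mean(D[, j], na.rm = TRUE)
  }
  Ds <- scale_columns(D)
  sv <- svd(Ds, nu = 0, nv = max(k, 2))
  rank <- sum(sv$d > 1e-8 * sv$d[1])
  if (k > rank) stop("k exceeds the rank of the dosage matrix")
  scores <- Ds %*% sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    load <- sv$v[, j]
    if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(dosages)
  scores
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with defaults equal to
#' the documented design decisions: a 10 x 10 penalty grid, 10,000
#' bootstrap iterations on 75\% subsamples drawn without replacement, PCs
#' excluded from scores, and median-based summaries.
#'
#' @param cohort A \code{\link{cohort_config}} for the simulate stage (the
#'   default pipeline runs on a synthetic cohort).
#' @param penalties Grid values per axis.
#' @param B Bootstrap/null iteration count.
#' @param frac Subsample fraction.
#' @param seed Integer seed for every stochastic stage.
#' @param measures Clinical measures analyzed.
#' @param exclude_features,exclude_subjects Optional exclusion lists.
#' @param replace Subsample with replacement.
#' @param include_pcs_in_scores Include PC features in the polygenic
#'   scores.
#' @param scan Run the univariate SNP scan stage (expensive; off by
#'   default).
#' @return Object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            penalties = seq(0.1, 1, by = 0.1),
                            B = 10000L, frac = 0.75, seed = 1L,
                            measures = measure_names(),
                            exclude_features = character(),
                            exclude_subjects = character(),
                            replace = FALSE,
                            include_pcs_in_scores = FALSE,
                            scan = FALSE) {
  structure(list(cohort = cohort, penalties = penalties, B = as.integer(B),
                 frac = frac, seed = as.integer(seed), measures = measures,
                 exclude_features = exclude_features,
                 exclude_subjects = exclude_subjects, replace = replace,
                 include_pcs_in_scores = include_pcs_in_scores,
                 scan = scan),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields override the defaults of \code{\link{pipeline_config}} and
#' \code{\link{cohort_config}}; unknown keys are an error.
#'
#' @param path YAML file.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort_args <- if (is.null(y$cohort)) list() else y$cohort
  cohort_keys <- intersect(names(cohort_args), names(formals(cohort_config)))
  unknown <- setdiff(names(cohort_args), names(formals(cohort_config)))
  if (length(unknown))
    stop("unknown cohort config keys: ", paste(unknown, collapse = ", "))
  cohort <- do.call(cohort_config, cohort_args[cohort_keys])
  rest <- y[setdiff(names(y), "cohort")]
  unknown <- setdiff(names(rest), names(formals(pipeline_config)))
  if (length(unknown))
    stop("unknown pipeline config keys: ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, c(list(cohort = cohort), rest))
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass_deep(config), tmp, auto_unbox = TRUE,
                       digits = NA)
  file_md5(tmp)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Run the full analysis pipeline
#'
#' Executes the eight stages end to end -- simulate, trajectories, scale,
#' grid, bootstrap, null, score, associate -- writing each stage's output
#' and a provenance manifest (config echo, config hash, seed, package
#' version, and per-file checksums) into \code{outdir}.  Identical config
#' and seed give identical stage-output checksums.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @param outdir Output directory.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "sccaPRS",
                   version = as.character(utils::packageVersion("sccaPRS")),
                   seed = config$seed,
                   config_hash = config_hash(config),
                   config = unclass_deep(config),
                   stages = list())
  paths <- character()
  stage <- function(name, fun) {
    out <- tryCatch(fun(), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    out
  }
  record <- function(name, files) {
    manifest$stages[[name]] <<- lapply(files, function(f)
      list(file = basename(f), md5 = file_md5(f)))
    paths <<- c(paths, files)
  }

  # 1. simulate
  cohort <- stage("simulate", function() simulate_cohort(config$cohort))
  sim_paths <- write_cohort(cohort, file.path(outdir, "cohort"))
  record("simulate", as.list(sim_paths))

  # 2. trajectories
  est <- stage("trajectories", function()
    fit_all_trajectories(cohort$clinical, cohort$covariates,
                         config$measures))
  f_est <- file.path(outdir, "trajectories.tsv")
  write_tsv_table(est, f_est)
  record("trajectories", list(f_est))

  # 3. scale
  X <- stage("scale", function() scale_intercepts(est, config$measures))
  f_x <- file.path(outdir, "clinical_matrix.tsv")
  write_tsv_table(data.frame(subject_id = rownames(X), X,
                             check.names = FALSE), f_x)
  record("scale", list(f_x))

  keep_subj <- setdiff(rownames(X), config$exclude_subjects)
  keep_feat <- setdiff(colnames(cohort$genotypes), config$exclude_features)
  X <- X[keep_subj, , drop = FALSE]
  G <- cohort$genotypes[keep_subj, keep_feat, drop = FALSE]
  attr(G, "feature_type") <-
    attr(cohort$genotypes, "feature_type")[
      match(keep_feat, colnames(cohort$genotypes))]
  Z <- scale_columns(G)

  # 4. grid
  grid <- stage("grid", function() scca_grid_search(X, Z, config$penalties))
  f_grid <- file.path(outdir, "grid.tsv")
  write_tsv_table(grid$cells, f_grid)
  record("grid", list(f_grid))

  # 5. bootstrap
  boot <- stage("bootstrap", function()
    bootstrap_scca(X, Z, unname(grid$best["penalty_x"]), unname(grid$best["penalty_z"]),
                   B = config$B, frac = config$frac, seed = config$seed,
                   replace = config$replace))
  f_boot <- file.path(outdir, "bootstrap.json")
  jsonlite::write_json(list(
    median_rho = boot$median_rho, rho_ci = boot$rho_ci,
    median_weight = as.list(boot$median_weight),
    selection_pct = as.list(boot$selection_pct),
    clinical_selection_pct = as.list(boot$clinical_selection_pct),
    B = boot$B, frac = boot$frac, seed = boot$seed,
    penalty_x = unname(boot$penalty_x), penalty_z = unname(boot$penalty_z)),
    f_boot, auto_unbox = TRUE, digits = NA)
  record("bootstrap", list(f_boot))

  # 6. null
  nul <- stage("null", function()
    permutation_null(X, Z, unname(grid$best["penalty_x"]), unname(grid$best["penalty_z"]),
                     B = config$B, frac = config$frac,
                     seed = config$seed + 1L,
                     observed_rho = boot$median_rho,
                     replace = config$replace))
  f_null <- file.path(outdir, "null.json")
  jsonlite::write_json(list(
    p_value = nul$p_value, p_value_add_one = nul$p_value_add_one,
    observed_rho = nul$observed_rho,
    median_null_rho = stats::median(nul$rho, na.rm = TRUE),
    clinical_selection_pct = as.list(nul$clinical_selection_pct),
    genetic_selection_pct = as.list(nul$genetic_selection_pct)),
    f_null, auto_unbox = TRUE, digits = NA)
  record("null", list(f_null))

  # 7. score
  weights <- median_weights(boot)
  scores <- stage("score", function()
    compute_scores(G, weights, include_pcs = config$include_pcs_in_scores))
  f_w <- file.path(outdir, "weights.tsv")
  f_s <- file.path(outdir, "scores.tsv")
  write_tsv_table(as.data.frame(weights), f_w)
  write_tsv_table(scores, f_s)
  record("score", list(f_w, f_s))

  # 8. associate
  assoc <- stage("associate", function() {
    intercepts <- trajectory_matrix(est, "intercept", config$measures)
    slopes <- trajectory_matrix(est, "slope", config$measures)
    list(baseline = spearman_assoc(scores, intercepts),
         decline = spearman_assoc(scores, slopes))
  })
  f_ab <- file.path(outdir, "assoc_baseline.tsv")
  f_ad <- file.path(outdir, "assoc_decline.tsv")
  write_tsv_table(assoc$baseline, f_ab)
  write_tsv_table(assoc$decline, f_ad)
  record("associate", list(f_ab, f_ad))

  if (isTRUE(config$scan)) {
    scan <- stage("scan", function()
      per_snp_scan(cohort$clinical, cohort$covariates, cohort$genotypes,
                   config$measures))
    f_sc <- file.path(outdir, "scan_p.tsv")
    write_tsv_table(data.frame(snp = rownames(scan$p), scan$p,
                               check.names = FALSE), f_sc)
    record("scan", list(f_sc))
  }

  f_manifest <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, f_manifest, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
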