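#' Summary-data container for multivariable Mendelian randomization
#'
#' Bundles harmonized GWAS summary statistics for L genetic variants
#' (instruments), K exposures and one outcome, together with the per-SNP
#' K x K covariance matrices of the SNP-exposure estimation errors.  Every
#' statistic in the package consumes this object.
#'
#' @param exposure_beta L x K numeric matrix of SNP-exposure association
#'   estimates (one column per exposure, per-allele units of each trait).
#' @param exposure_se L x K numeric matrix of the corresponding standard
#'   errors (strictly positive).
#' @param outcome_beta length-L numeric vector of SNP-outcome association
#'   estimates.
#' @param outcome_se length-L numeric vector of SNP-outcome standard errors
#'   (strictly positive).
#' @param snp_cov list of L symmetric K x K matrices: the covariance of the
#'   estimation errors of SNP j's exposure associations.  Diagonals must
#'   agree with `exposure_se[j, ]^2`.  Use [snpcov_phenocorr()],
#'   [snpcov_individual()] or [snpcov_zero()] to construct these.
#' @param snp_ids optional character vector of variant identifiers
#'   (defaults to rownames of `exposure_beta` or `snp_1..L`).
#' @param exposure_names optional character vector of exposure names
#'   (defaults to colnames of `exposure_beta` or `X1..K`).
#'
#' @details
#' Invariants enforced at construction: `L >= K + 1` (positive residual
#' degrees of freedom `L - K` for the heterogeneity test), strictly positive
#' standard errors everywhere, symmetric per-SNP covariance matrices whose
#' diagonal matches the squared exposure standard errors (relative tolerance
#' 1e-8), and positive semi-definiteness of each covariance matrix.  Matrices
#' that fail PSD only by numerical noise (most negative eigenvalue smaller in
#' magnitude than 1e-6 times the largest eigenvalue) are repaired by clipping
#' eigenvalues at zero; larger violations are an error, since a covariance
#' built from a valid correlation matrix is PSD by construction and a large
#' violation signals bad input.
#'
#' Allele harmonization and LD clumping are assumed done upstream.
#'
#' @return An object of class `mvmr_dataset`: a list with elements
#'   `snp_ids`, `exposure_names`, `exposure_beta`, `exposure_se`,
#'   `outcome_beta`, `outcome_se`, `snp_cov`, `L`, `K`.
#' @seealso [read_mvmr_summary()], [validate_mvmr_dataset()]
#' @export
#' @examples
#' d <- mvmr_dataset(
#'   exposure_beta = cbind(x1 = c(.1, .2, .3, .15), x2 = c(.05, .1, .2, .1)),
#'   exposure_se   = matrix(0.05, 4, 2),
#'   outcome_beta  = c(.02, .05, .08, .04),
#'   outcome_se    = rep(0.05, 4),
#'   snp_cov       = snpcov_zero(matrix(0.05, 4, 2))
#' )
#' d
mvmr_dataset <- function(exposure_beta, exposure_se, outcome_beta, outcome_se,
                         snp_cov, snp_ids = NULL, exposure_names = NULL) {
  exposure_beta <- as.matrix(exposure_beta)
  exposure_se <- as.matrix(exposure_se)
  L <- nrow(exposure_beta)
  K <- ncol(exposure_beta)

  if (is.null(exposure_names)) {
    exposure_names <- colnames(exposure_beta)
    if (is.null(exposure_names)) exposure_names <- paste0("X", seq_len(K))
  }
  if (is.null(snp_ids)) {
    snp_ids <- rownames(exposure_beta)
    if (is.null(snp_ids)) snp_ids <- paste0("snp_", seq_len(L))
  }
  snp_ids <- as.character(snp_ids)

  if (L < K + 1L) {
    stop("need at least K + 1 = ", K + 1L, " SNPs for a model with K = ", K,
         " exposures; got L = ", L, call. = FALSE)
  }
  if (!identical(dim(exposure_se), dim(exposure_beta))) {
    stop("exposure_se must have the same dimensions as exposure_beta",
         call. = FALSE)
  }
  if (length(outcome_beta) != L || length(outcome_se) != L) {
    stop("outcome_beta and outcome_se must have length L = ", L, call. = FALSE)
  }
  if (!all(is.finite(exposure_beta)) || !all(is.finite(exposure_se)) ||
      !all(is.finite(outcome_beta)) || !all(is.finite(outcome_se))) {
    stop("all summary statistics must be finite; drop incomplete SNPs first",
         call. = FALSE)
  }
  bad_se <- which(exposure_se <= 0, arr.ind = TRUE)
  if (nrow(bad_se) > 0) {
    stop("nonpositive exposure standard error for SNP '",
         snp_ids[bad_se[1, 1]], "', exposure '",
         exposure_names[bad_se[1, 2]], "'", call. = FALSE)
  }
  if (any(outcome_se <= 0)) {
    stop("nonpositive outcome standard error for SNP '",
         snp_ids[which(outcome_se <= 0)[1]], "'", call. = FALSE)
  }
  if (!is.list(snp_cov) || length(snp_cov) != L) {
    stop("snp_cov must be a list of L = ", L, " K x K matrices", call. = FALSE)
  }

  snp_cov <- lapply(seq_len(L), function(j) {
    S <- as.matrix(snp_cov[[j]])
    if (!identical(dim(S), c(K, K))) {
      stop("snp_cov[[", j, "]] is not ", K, " x ", K, call. = FALSE)
    }
    if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S)))) {
      stop("snp_cov[[", j, "]] (SNP '", snp_ids[j], "') is not symmetric",
           call. = FALSE)
    }
    S <- (S + t(S)) / 2
    dd <- abs(diag(S) - exposure_se[j, ]^2)
    rel <- dd / pmax(exposure_se[j, ]^2, .Machine$double.xmin)
    if (any(rel > 1e-8)) {
      stop("diag(snp_cov[[", j, "]]) disagrees with exposure_se^2 for SNP '",
           snp_ids[j], "' (max relative discrepancy ",
           format(max(rel), digits = 3), ")", call. = FALSE)
    }
    .psd_project(S, snp = snp_ids[j])
  })

  dimnames(exposure_beta) <- dimnames(exposure_se) <- list(snp_ids, exposure_names)
  structure(
    list(snp_ids = snp_ids, exposure_names = exposure_names,
         exposure_beta = exposure_beta, exposure_se = exposure_se,
         outcome_beta = as.numeric(outcome_beta),
         outcome_se = as.numeric(outcome_se),
         snp_cov = snp_cov, L = L, K = K),
    class = "mvmr_dataset")
}

# Clip tiny negative eigenvalues to zero; refuse to repair real violations.
.psd_project <- function(S, snp = "?", tol = 1e-6) {
  ev <- eigen(S, symmetric = TRUE)
  lam <- ev$values
  if (all(lam >= 0)) return(S)
  scale <- max(abs(lam))
  if (min(lam) < -tol * scale) {
    stop("snp_cov for SNP '", snp, "' is not positive semi-definite ",
         "(min eigenvalue ", format(min(lam), digits = 4),
         "); this exceeds numerical noise and signals invalid input",
         call. = FALSE)
  }
  lam[lam < 0] <- 0
  ev$vectors %*% (lam * t(ev$vectors))
}

#' @export
print.mvmr_dataset <- function(x, ...) {
  cat("<mvmr_dataset>  L =", x$L, "SNPs,  K =", x$K, "exposures:",
      paste(x$exposure_names, collapse = ", "), "\n")
  off <- vapply(x$snp_cov, function(S) sum(abs(S[upper.tri(S)])), 0)
  cat("  SNP-exposure error covariances:",
      if (all(off == 0)) "diagonal (zero-covariance route)" else "full", "\n")
  invisible(x)
}

#' Check an MVMR summary dataset against its invariants
#'
#' Pure reporting companion to [mvmr_dataset()]: returns a character vector of
#' human-readable violations (empty when the object is internally consistent)
#' and never errors or mutates its input.  Useful on objects assembled by hand
#' or deserialized from disk.
#'
#' @param dataset an `mvmr_dataset` (or structurally similar list).
#' @return character vector of violation messages; `character(0)` if clean.
#' @export
validate_mvmr_dataset <- function(dataset) {
  v <- character(0)
  req <- c("exposure_beta", "exposure_se", "outcome_beta", "outcome_se",
           "snp_cov", "snp_ids", "exposure_names")
  missing_f <- setdiff(req, names(dataset))
  if (length(missing_f)) {
    return(paste("missing field(s):", paste(missing_f, collapse = ", ")))
  }
  B <- as.matrix(dataset$exposure_beta)
  S <- as.matrix(dataset$exposure_se)
  L <- nrow(B); K <- ncol(B)
  ids <- as.character(dataset$snp_ids)

  if (L < K + 1L) v <- c(v, sprintf("L = %d < K + 1 = %d", L, K + 1L))
  bad <- which(S <= 0, arr.ind = TRUE)
  for (r in seq_len(nrow(bad))) {
    v <- c(v, sprintf("nonpositive exposure_se for SNP '%s', exposure '%s'",
                      ids[bad[r, 1]], dataset$exposure_names[bad[r, 2]]))
  }
  for (j in which(dataset$outcome_se <= 0)) {
    v <- c(v, sprintf("nonpositive outcome_se for SNP '%s'", ids[j]))
  }
  if (!all(is.finite(B)) || !all(is.finite(S)) ||
      !all(is.finite(dataset$outcome_beta)) ||
      !all(is.finite(dataset$outcome_se))) {
    v <- c(v, "non-finite summary statistics present")
  }
  if (!is.list(dataset$snp_cov) || length(dataset$snp_cov) != L) {
    v <- c(v, sprintf("snp_cov is not a list of length L = %d", L))
    return(v)
  }
  max_rel <- 0; worst <- NA_character_
  for (j in seq_len(L)) {
    Sj <- as.matrix(dataset$snp_cov[[j]])
    if (!identical(dim(Sj), c(K, K))) {
      v <- c(v, sprintf("snp_cov[[%d]] is not %d x %d", j, K, K)); next
    }
    if (max(abs(Sj - t(Sj))) > 1e-8 * max(1, max(abs(Sj)))) {
      v <- c(v, sprintf("snp_cov for SNP '%s' is not symmetric", ids[j]))
    }
    if (all(S[j, ] > 0)) {
      rel <- max(abs(diag(Sj) - S[j, ]^2) / S[j, ]^2)
      if (rel > max_rel) { max_rel <- rel; worst <- ids[j] }
    }
    lam <- eigen((Sj + t(Sj)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(lam) < -1e-6 * max(abs(lam), .Machine$double.xmin)) {
      v <- c(v, sprintf("snp_cov for SNP '%s' is not positive semi-definite",
                        ids[j]))
    }
  }
  if (max_rel > 1e-8) {
    v <- c(v, sprintf(
      "diag(snp_cov) disagrees with exposure_se^2 (max relative discrepancy %.3g at SNP '%s')",
      max_rel, worst))
  }
  v
}

#' Read harmonized summary-statistic tables into an MVMR dataset
#'
#' Joins a SNP-exposure table and a SNP-outcome table on variant identifier
#' and attaches per-SNP covariance matrices from one of the three supported
#' sources.  This is the formatting step of the MVMR workflow: everything
#' downstream (strength, pleiotropy, estimation) consumes its output.
#'
#' @param exposure_file delimited text file with a `SNP` column followed by a
#'   `<name>_beta` and `<name>_se` column pair per exposure.
#' @param outcome_file delimited text file with columns `SNP`, `beta`, `se`.
#' @param cov_source one of: the string `"zero"` (no covariance information;
#'   valid only under the global null -- a warning is emitted), the path to a
#'   K x K phenotypic correlation matrix file (header row naming the
#'   exposures in the same order as the exposure table; see
#'   [snpcov_phenocorr()]), or the path to a long-format per-SNP covariance
#'   file with columns `SNP`, `row`, `col`, `cov` as written by
#'   [write_mvmr_summary()].
#' @param sep field separator for all files (default tab).
#'
#' @details SNPs present in only one table are dropped with a message; rows
#'   with any missing or non-finite field are likewise dropped with a message.
#'   The output row order follows the exposure file (first-file order), so
#'   identical inputs always produce identical datasets.  Effect alleles must
#'   already be harmonized between the two tables.
#' @return an [mvmr_dataset()].
#' @export
read_mvmr_summary <- function(exposure_file, outcome_file, cov_source = "zero",
                              sep = "\t") {
  ex <- utils::read.table(exposure_file, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  out <- utils::read.table(outcome_file, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!"SNP" %in% names(ex)) stop("exposure table lacks a 'SNP' column")
  if (!all(c("SNP", "beta", "se") %in% names(out))) {
    stop("outcome table must have columns SNP, beta, se")
  }
  beta_cols <- grep("_beta$", names(ex), value = TRUE)
  exposures <- sub("_beta$", "", beta_cols)
  se_cols <- paste0(exposures, "_se")
  if (!all(se_cols %in% names(ex))) {
    stop("exposure table lacks <name>_se columns for: ",
         paste(exposures[!se_cols %in% names(ex)], collapse = ", "))
  }
  K <- length(exposures)

  keep <- ex$SNP %in% out$SNP
  n_dropped <- sum(!keep) + sum(!out$SNP %in% ex$SNP)
  ex <- ex[keep, , drop = FALSE]
  out <- out[match(ex$SNP, out$SNP), , drop = FALSE]

  B <- as.matrix(ex[, beta_cols, drop = FALSE])
  S <- as.matrix(ex[, se_cols, drop = FALSE])
  ob <- as.numeric(out$beta); os <- as.numeric(out$se)
  complete <- rowSums(!is.finite(B)) == 0 & rowSums(!is.finite(S)) == 0 &
    is.finite(ob) & is.finite(os)
  n_dropped <- n_dropped + sum(!complete)
  if (n_dropped > 0) {
    message("read_mvmr_summary: dropped ", n_dropped,
            " SNP(s) (unmatched between tables or with missing fields)")
  }
  B <- B[complete, , drop = FALSE]; S <- S[complete, , drop = FALSE]
  ob <- ob[complete]; os <- os[complete]
  ids <- ex$SNP[complete]
  if (nrow(B) < K + 1L) {
    stop("only ", nrow(B), " usable SNP(s) after intersecting tables; ",
         "need at least ", K + 1L, " for K = ", K, " exposures")
  }
  colnames(B) <- colnames(S) <- exposures

  if (identical(cov_source, "zero")) {
    cov_list <- snpcov_zero(S)
    warning("covariance source \"zero\": SNP-exposure error covariances are ",
            "assumed absent. This is correct only when the exposure ",
            "associations come from mutually independent samples (or under ",
            "the global null); with correlated exposures it can make the ",
            "conditional F-statistic and beta_Q,het uninterpretable.",
            call. = FALSE)
  } else if (is.character(cov_source) && file.exists(cov_source)) {
    probe <- utils::read.table(cov_source, header = TRUE, sep = sep,
                               stringsAsFactors = FALSE, check.names = FALSE)
    if (all(c("SNP", "row", "col", "cov") %in% names(probe))) {
      cov_list <- .covlist_from_long(probe, ids, exposures)
    } else {
      rho <- as.matrix(probe)
      if (!identical(colnames(rho), exposures)) {
        stop("phenotypic correlation file header must name the exposures ",
             "in exposure-table order: ", paste(exposures, collapse = ", "))
      }
      cov_list <- snpcov_phenocorr(rho, S)
    }
  } else if (is.matrix(cov_source)) {
    cov_list <- snpcov_phenocorr(cov_source, S)
  } else {
    stop("cov_source must be \"zero\", a correlation matrix (or file), ",
         "or a long-format per-SNP covariance file")
  }

  mvmr_dataset(B, S, ob, os, cov_list, snp_ids = ids,
               exposure_names = exposures)
}

.covlist_from_long <- function(long, ids, exposures) {
  K <- length(exposures)
  lapply(ids, function(id) {
    rows <- long[long$SNP == id, , drop = FALSE]
    if (nrow(rows) == 0) stop("no covariance entries for SNP '", id, "'")
    S <- matrix(0, K, K, dimnames = list(exposures, exposures))
    ri <- match(rows$row, exposures); ci <- match(rows$col, exposures)
    if (anyNA(ri) || anyNA(ci)) {
      stop("covariance file names exposures absent from the exposure table")
    }
    S[cbind(ri, ci)] <- rows$cov
    S[cbind(ci, ri)] <- rows$cov
    S
  })
}

#' Write an MVMR dataset to delimited text files
#'
#' Inverse of [read_mvmr_summary()]: writes the exposure table, outcome table
#' and a long-format per-SNP covariance file.  Numbers are written with 17
#' significant digits so a write-then-read round trip reproduces every field
#' bit-identically.
#'
#' @param dataset an [mvmr_dataset()].
#' @param exposure_file,outcome_file,cov_file output paths; `cov_file = NULL`
#'   skips the covariance file.
#' @param sep field separator (default tab).
#' @return invisibly, the paths written.
#' @export
write_mvmr_summary <- function(dataset, exposure_file, outcome_file,
                               cov_file = NULL, sep = "\t") {
  fmt <- function(x) sprintf("%.17g", x)
  K <- dataset$K
  ex <- data.frame(SNP = dataset$snp_ids, stringsAsFactors = FALSE)
  for (k in seq_len(K)) {
    ex[[paste0(dataset$exposure_names[k], "_beta")]] <- fmt(dataset$exposure_beta[, k])
    ex[[paste0(dataset$exposure_names[k], "_se")]] <- fmt(dataset$exposure_se[, k])
  }
  utils::write.table(ex, exposure_file, sep = sep, quote = FALSE,
                     row.names = FALSE)
  out <- data.frame(SNP = dataset$snp_ids, beta = fmt(dataset$outcome_beta),
                    se = fmt(dataset$outcome_se), stringsAsFactors = FALSE)
  utils::write.table(out, outcome_file, sep = sep, quote = FALSE,
                     row.names = FALSE)
  paths <- c(exposure_file, outcome_file)
  if (!is.null(cov_file)) {
    idx <- which(upper.tri(diag(K), diag = TRUE), arr.ind = TRUE)
    long <- do.call(rbind, lapply(seq_len(dataset$L), function(j) {
      data.frame(SNP = dataset$snp_ids[j],
                 row = dataset$exposure_names[idx[, 1]],
                 col = dataset$exposure_names[idx[, 2]],
                 cov = fmt(dataset$snp_cov[[j]][idx]),
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(long, cov_file, sep = sep, quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, cov_file)
  }
  invisible(paths)
}

#' Restrict an MVMR dataset to a subset of exposures or SNPs
#'
#' @param dataset an [mvmr_dataset()].
#' @param exposures integer or character vector selecting exposures.
#' @param snps integer or character vector selecting SNPs.
#' @return an [mvmr_dataset()] restricted accordingly.
#' @export
subset_mvmr <- function(dataset, exposures = NULL, snps = NULL) {
  ei <- seq_len(dataset$K)
  if (!is.null(exposures)) {
    ei <- if (is.character(exposures)) match(exposures, dataset$exposure_names) else as.integer(exposures)
    if (anyNA(ei)) stop("unknown exposure selection")
  }
  si <- seq_len(dataset$L)
  if (!is.null(snps)) {
    si <- if (is.character(snps)) match(snps, dataset$snp_ids) else as.integer(snps)
    if (anyNA(si)) stop("unknown SNP selection")
  }
  mvmr_dataset(dataset$exposure_beta[si, ei, drop = FALSE],
               dataset$exposure_se[si, ei, drop = FALSE],
               dataset$outcome_beta[si], dataset$outcome_se[si],
               lapply(dataset$snp_cov[si], function(S) S[ei, ei, drop = FALSE]),
               snp_ids = dataset$snp_ids[si],
               exposure_names = dataset$exposure_names[ei])
}
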