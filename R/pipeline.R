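# Dataset assembly and workflow orchestration.

#' Featurize a cleaned molecule set
#'
#' Computes descriptors and dictionary fingerprints for every molecule,
#' dropping (with reason \code{descriptor_fail}) molecules whose
#' descriptors cannot be computed. Column provenance
#' (\code{"descriptor"}/\code{"fingerprint"}) is kept as an attribute.
#'
#' @param molecules data.frame with \code{id}, \code{smiles} and optionally
#'   \code{activity} (e.g. from \code{\link{parse_and_clean}}).
#' @param descriptors descriptor names (default: full registry); NULL skips
#'   descriptors.
#' @param dictionaries list of \code{"fp_dictionary"} objects (default:
#'   none).
#' @return List with \code{features} (numeric matrix, rownames = molecule
#'   ids, attribute \code{provenance}), \code{activity}, \code{molecules}
#'   (retained rows) and \code{rejections}.
#' @export
featurize_molecules <- function(molecules,
                                descriptors = descriptor_registry(),
                                dictionaries = list()) {
  .check(nrow(molecules) > 0, "featurize_molecules: empty molecule set")
  blocks <- list()
  prov <- character(0)
  failed <- integer(0)
  if (!is.null(descriptors) && length(descriptors)) {
    D <- compute_descriptors(molecules$smiles, descriptors)
    failed <- attr(D, "failed")
    blocks$desc <- D
    prov <- c(prov, rep("descriptor", ncol(D)))
  }
  for (dict in dictionaries) {
    FP <- compute_fingerprint(molecules$smiles, dict)
    blocks[[length(blocks) + 1L]] <- FP
    prov <- c(prov, rep("fingerprint", ncol(FP)))
  }
  .check(length(blocks) > 0, "featurize_molecules: nothing to compute")
  X <- do.call(cbind, blocks)
  keep <- setdiff(seq_len(nrow(molecules)), failed)
  .check(length(keep) > 0, "featurize_molecules: all molecules failed")
  rej <- if (length(failed)) {
    data.frame(id = molecules$id[failed], reason = "descriptor_fail",
               detail = molecules$smiles[failed], stringsAsFactors = FALSE)
  } else {
    data.frame(id = character(0), reason = character(0),
               detail = character(0), stringsAsFactors = FALSE)
  }
  X <- X[keep, , drop = FALSE]
  rownames(X) <- molecules$id[keep]
  attr(X, "provenance") <- stats::setNames(prov, colnames(X))
  list(features = X,
       activity = if ("activity" %in% names(molecules))
         molecules$activity[keep] else NULL,
       molecules = molecules[keep, , drop = FALSE],
       rejections = rej)
}

#' Remove constant and highly correlated feature columns
#'
#' First removes zero-variance columns; then scans the remaining columns in
#' descending variance order and greedily removes any column whose absolute
#' Pearson correlation with an already-kept column exceeds the threshold
#' (the kept, higher-variance column wins). Variance ties break on column
#' name, so the result is deterministic and invariant to input column
#' order.
#'
#' @param table numeric feature matrix with named columns.
#' @param corr_threshold correlation threshold (default 0.95).
#' @return Filtered matrix with attribute \code{removed}: data.frame
#'   (feature, reason, partner).
#' @export
filter_features <- function(table, corr_threshold = 0.95) {
  X <- as.matrix(table)
  .check(ncol(X) >= 1, "filter_features: no columns")
  .check(!is.null(colnames(X)), "filter_features: columns must be named")
  v <- apply(X, 2L, stats::var)
  removed <- data.frame(feature = character(0), reason = character(0),
                        partner = character(0), stringsAsFactors = FALSE)
  zv <- colnames(X)[v == 0 | !is.finite(v)]
  if (length(zv)) {
    removed <- rbind(removed,
                     data.frame(feature = zv, reason = "zero_variance",
                                partner = NA_character_))
    X <- X[, setdiff(colnames(X), zv), drop = FALSE]
    v <- v[setdiff(names(v), zv)]
  }
  .check(ncol(X) > 0, "filter_features: all columns removed")
  ord <- colnames(X)[order(-v, colnames(X), method = "radix")]
  kept <- character(0)
  for (nm in ord) {
    if (length(kept)) {
      r <- abs(stats::cor(X[, nm], X[, kept, drop = FALSE]))
      hit <- which(r > corr_threshold)
      if (length(hit)) {
        removed <- rbind(removed, data.frame(
          feature = nm, reason = "correlated",
          partner = kept[hit[1L]], stringsAsFactors = FALSE))
        next
      }
    }
    kept <- c(kept, nm)
  }
  out <- X[, kept[order(match(kept, colnames(X)))], drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' Stratified train/test split on the activity distribution
#'
#' Bins the activity into \code{n_bins} equal-frequency bins and samples
#' \code{test_fraction} of each bin (rounded) into the test set without
#' replacement, so the two sets share the activity distribution. Bins that
#' end up with fewer than 2 molecules are merged into their neighbor with a
#' warning.
#'
#' @param ids molecule identifiers.
#' @param activity numeric activity values aligned with \code{ids}.
#' @param test_fraction fraction held out (0 < f < 1; default 0.325).
#' @param n_bins stratification bins (default 10).
#' @param seed integer seed; identical seeds give identical splits.
#' @return An object of class \code{"dataset_split"}: list with
#'   \code{train_ids}, \code{test_ids}, \code{seed}, \code{test_fraction},
#'   \code{n_bins}.
#' @export
split_dataset <- function(ids, activity, test_fraction = 0.325,
                          n_bins = 10, seed = 1) {
  n <- length(ids)
  .check(n == length(activity), "split_dataset: length mismatch")
  .check(test_fraction > 0 && test_fraction < 1,
         "split_dataset: test_fraction must be in (0,1)")
  .check(n >= 2 * n_bins, "split_dataset: need at least 2 molecules per bin")
  bins <- discretize(activity, n_bins)
  # merge undersized bins into the neighbor below (or above for bin 0)
  repeat {
    sizes <- table(bins)
    small <- names(sizes)[sizes < 2]
    if (!length(small)) break
    b <- as.integer(small[1L])
    tgt <- if (any(bins < b)) max(bins[bins < b]) else min(bins[bins > b])
    warning(sprintf("split_dataset: merging undersized bin %d into %d",
                    b, tgt))
    bins[bins == b] <- tgt
  }
  test_idx <- with_seed(seed, {
    unlist(lapply(sort(unique(bins)), function(b) {
      idx <- which(bins == b)
      k <- max(1L, min(length(idx) - 1L,
                       round(test_fraction * length(idx))))
      idx[sample.int(length(idx), k)]
    }), use.names = FALSE)
  })
  test_idx <- sort(test_idx)
  structure(list(train_ids = ids[-test_idx], test_ids = ids[test_idx],
                 seed = seed, test_fraction = test_fraction,
                 n_bins = n_bins),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  n <- length(x$train_ids) + length(x$test_ids)
  cat(sprintf(
    "Stratified split: %d train / %d test (%.1f%% held out, %d bins, seed %d)\n",
    length(x$train_ids), length(x$test_ids),
    100 * length(x$test_ids) / n, x$n_bins, x$seed))
  invisible(x)
}

# ---- workflow configuration ----------------------------------------------

#' Default workflow configuration
#'
#' A named list of all workflow knobs: feature choices, filter thresholds,
#' feature-selection size, learner roster, consensus exclusions, AD
#' multiplier and the master seed. Serializable to a flat key/value text
#' file via \code{\link{write_workflow_config}}.
#'
#' @param ... overrides of default entries (unknown keys are an error).
#' @return A list of class \code{"workflow_config"}.
#' @export
workflow_config <- function(...) {
  cfg <- list(
    descriptor_set = "registry",        # registry | none
    fingerprint_dicts = "substructure,pubchem",
    corr_threshold = 0.95,
    select_k = 40,
    target_bins = 5,
    feature_bins = 10,
    learners = "knn,rf,svm,gbm,rvm",
    knn_k = 5,
    consensus_exclude = "",
    ad_multiplier = 3,
    test_fraction = 0.325,
    split_bins = 10,
    cv_folds = 10,
    activity_min = 0,
    activity_max = 7,
    alert_threshold = 3,
    mae_threshold = 1,
    seed = 1
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  .check(length(bad) == 0,
         sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  cfg[names(dots)] <- dots
  class(cfg) <- "workflow_config"
  cfg
}

#' Write a workflow config as flat key = value text
#' @param config a \code{"workflow_config"}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_workflow_config <- function(config, path) {
  lines <- vapply(names(config), function(k)
    sprintf("%s = %s", k, format(config[[k]], scientific = FALSE)), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a workflow config written by \code{\link{write_workflow_config}}
#' @param path file path.
#' @return A \code{"workflow_config"}; numeric-looking values are restored
#'   to numbers, so a write/read round-trip is lossless.
#' @export
read_workflow_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  keys <- trimws(vapply(kv, `[[`, "", 2L))
  vals <- trimws(vapply(kv, `[[`, "", 3L))
  parsed <- lapply(vals, function(v) {
    nv <- suppressWarnings(as.numeric(v))
    if (!is.na(nv) && grepl("^-?[0-9.eE+-]+$", v)) nv else v
  })
  do.call(workflow_config, stats::setNames(parsed, keys))
}

# Split comma-separated config lists.
.cfg_list <- function(s) {
  if (is.null(s) || !nzchar(s)) character(0)
  else trimws(strsplit(s, ",", fixed = TRUE)[[1L]])
}

.cfg_learner_spec <- function(name, cfg) {
  switch(name,
         knn = learner_spec("knn", k = cfg$knn_k),
         learner_spec(name))
}

#' Run the full consensus QSAR workflow
#'
#' featurize -> filter -> select -> split -> train all learners ->
#' consensus -> metrics -> applicability domain -> interpretation, on a
#' molecule table (id, smiles, activity). Fully reproducible from
#' (config, data): every stochastic stage derives its seed from the
#' config's master seed.
#'
#' @param config a \code{\link{workflow_config}}.
#' @param data data.frame with \code{id}, \code{smiles}, \code{activity},
#'   or a path to a CSV with those columns.
#' @return An object of class \code{"qsar_workflow"}: list with
#'   \code{config}, \code{cleaning} (rejection log), \code{split},
#'   \code{selection} (feature ranking), \code{metrics} (one
#'   \code{metrics_report} per learner), \code{consensus} (metrics,
#'   excluded learners, predictions), \code{ad} (an \code{ad_report}),
#'   \code{alerts} (fragment contributions on selected fingerprint bits)
#'   and \code{scaffolds} (large-error scaffold table).
#' @export
run_workflow <- function(config, data) {
  .check(inherits(config, "workflow_config"), "run_workflow: bad config")
  if (is.character(data)) data <- utils::read.csv(data,
                                                  stringsAsFactors = FALSE)
  stage <- "clean"
  out <- tryCatch({
    cleaned <- parse_and_clean(data, config$activity_min,
                               config$activity_max)

    stage <- "featurize"
    dicts <- lapply(.cfg_list(config$fingerprint_dicts),
                    load_fingerprint_dictionary)
    desc <- if (identical(config$descriptor_set, "none")) NULL
            else descriptor_registry()
    feat <- featurize_molecules(cleaned$molecules, desc, dicts)
    X <- feat$features
    y <- feat$activity
    prov <- attr(X, "provenance")

    stage <- "filter"
    # the correlation filter is a descriptor-redundancy filter: fingerprint
    # bits form a separate block and only lose zero-variance columns
    desc_cols <- names(prov)[prov == "descriptor"]
    fp_cols <- names(prov)[prov == "fingerprint"]
    Xd <- if (length(desc_cols)) {
      filter_features(X[, desc_cols, drop = FALSE], config$corr_threshold)
    } else NULL
    Xp <- if (length(fp_cols)) {
      B <- X[, fp_cols, drop = FALSE]
      B[, apply(B, 2L, stats::var) > 0, drop = FALSE]
    } else NULL
    Xf <- do.call(cbind, Filter(Negate(is.null), list(Xd, Xp)))

    stage <- "select"
    k <- min(config$select_k, ncol(Xf))
    ranking <- rank_and_select(Xf, y, k, config$target_bins,
                               config$feature_bins)
    sel <- ranking$feature[ranking$selected]
    Xs <- Xf[, sel, drop = FALSE]

    stage <- "split"
    split <- split_dataset(rownames(Xs), y,
                           test_fraction = config$test_fraction,
                           n_bins = config$split_bins,
                           seed = derive_seed(config$seed, "split"))
    tr <- rownames(Xs) %in% split$train_ids
    # standardize descriptor columns on training statistics
    ctr <- colMeans(Xs[tr, , drop = FALSE])
    scl <- apply(Xs[tr, , drop = FALSE], 2L, stats::sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    Z <- sweep(sweep(Xs, 2L, ctr, "-"), 2L, scl, "/")
    ytr <- y[tr]; yte <- y[!tr]

    stage <- "train"
    learner_names <- .cfg_list(config$learners)
    .check(length(learner_names) >= 2, "run_workflow: need >= 2 learners")
    fits <- list(); pred_tr <- list(); pred_te <- list()
    metrics <- list()
    # parameter count charged in adjusted R2: the selected feature count,
    # capped so small datasets stay evaluable
    p_charged <- min(length(sel), length(ytr) - 2L)
    for (nm in learner_names) {
      spec <- .cfg_learner_spec(nm, config)
      fit <- fit_learner(spec, Z[tr, , drop = FALSE], ytr,
                         seed = derive_seed(config$seed, paste0("fit_", nm)))
      p_tr <- predict(fit, Z[tr, , drop = FALSE])
      p_te <- predict(fit, Z[!tr, , drop = FALSE])
      q2 <- if (config$cv_folds >= 2) {
        q2_cv(Z[tr, , drop = FALSE], ytr, spec, folds = config$cv_folds,
              seed = derive_seed(config$seed, paste0("cv_", nm)))$q2
      } else NA_real_
      fits[[nm]] <- fit
      pred_tr[[nm]] <- p_tr; pred_te[[nm]] <- p_te
      metrics[[nm]] <- metrics_report(ytr, p_tr, yte, p_te,
                                      p = p_charged, q2 = q2)
    }
    P_tr <- do.call(cbind, pred_tr); P_te <- do.call(cbind, pred_te)

    stage <- "consensus"
    excl <- intersect(.cfg_list(config$consensus_exclude), learner_names)
    cons_tr <- consensus_predict(P_tr, exclude = excl)
    cons_te <- consensus_predict(P_te, exclude = excl)
    cons_metrics <- metrics_report(ytr, cons_tr, yte, cons_te,
                                   p = p_charged)

    stage <- "domain"
    ad <- ad_assess(std_dm(P_tr), std_dm(P_te),
                    multiplier = config$ad_multiplier)

    stage <- "alerts"
    fp_sel <- sel[prov[sel] == "fingerprint"]
    alerts <- if (length(fp_sel)) {
      do.call(rbind, lapply(fp_sel, function(bit) {
        fc <- fragment_contribution(Xs[, bit], y,
                                    threshold = config$alert_threshold)
        if (is.null(fc)) return(NULL)
        data.frame(feature = bit, sign = fc$sign,
                   count_high = fc$count_high, count_low = fc$count_low,
                   cramers_v = ranking$cramers_v[ranking$feature == bit],
                   stringsAsFactors = FALSE)
      }))
    } else NULL

    stage <- "scaffolds"
    abs_err_te <- abs(yte - cons_te)
    scaffolds <- error_scaffold_table(
      feat$molecules, split,
      abs_errors = stats::setNames(abs_err_te, split$test_ids),
      mae_threshold = config$mae_threshold)

    structure(list(
      config = config,
      cleaning = rbind(cleaned$rejections, feat$rejections),
      n_molecules = nrow(Xs),
      selection = ranking,
      split = split,
      standardization = list(center = ctr, scale = scl),
      fits = fits,
      predictions = list(train = P_tr, test = P_te,
                         consensus_train = as.numeric(cons_tr),
                         consensus_test = as.numeric(cons_te)),
      metrics = metrics,
      consensus = list(metrics = cons_metrics, excluded = excl,
                       models = attr(cons_te, "models")),
      ad = ad,
      alerts = alerts,
      scaffolds = scaffolds,
      y = list(train = ytr, test = yte)
    ), class = "qsar_workflow")
  }, error = function(e) {
    stop(sprintf("workflow failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  out
}

#' @export
print.qsar_workflow <- function(x, ...) {
  cat(sprintf("Consensus QSAR workflow: %d molecules, %d selected features\n",
              x$n_molecules, sum(x$selection$selected)))
  print(x$split)
  for (nm in names(x$metrics)) {
    m <- x$metrics[[nm]]
    cat(sprintf("  %-5s q2_ext = %.3f  RMSE_test = %.3f  MAE_test = %.3f\n",
                nm, m$q2_ext, m$rmse_test, m$mae_test))
  }
  m <- x$consensus$metrics
  cat(sprintf("  consensus%s q2_ext = %.3f  RMSE_test = %.3f  MAE_test = %.3f\n",
              if (length(x$consensus$excluded))
                sprintf(" (except %s)",
                        paste(x$consensus$excluded, collapse = ",")) else "",
              m$q2_ext, m$rmse_test, m$mae_test))
  cat(sprintf("  AD coverage at multiplier %g: %.1f%%\n",
              x$ad$multiplier, x$ad$coverage))
  invisible(x)
}

#' Write a workflow report bundle
#'
#' JSON report (metrics, consensus, AD coverage, alerts, scaffolds,
#' cleaning log) plus a per-molecule CSV of test-set predictions.
#'
#' @param workflow a \code{"qsar_workflow"}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_workflow_report <- function(workflow, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(
    n_molecules = workflow$n_molecules,
    metrics = lapply(workflow$metrics, unclass),
    consensus = list(metrics = unclass(workflow$consensus$metrics),
                     excluded = workflow$consensus$excluded,
                     models = workflow$consensus$models),
    ad = list(reference = workflow$ad$reference,
              multiplier = workflow$ad$multiplier,
              coverage = workflow$ad$coverage),
    alerts = workflow$alerts,
    scaffolds = workflow$scaffolds,
    cleaning = workflow$cleaning,
    config = unclass(workflow$config)
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  preds <- data.frame(id = workflow$split$test_ids,
                      observed = workflow$y$test,
                      consensus = workflow$predictions$consensus_test,
                      workflow$predictions$test,
                      std_dm = workflow$ad$std_dm,
                      in_domain = workflow$ad$in_domain)
  utils::write.csv(preds, file.path(dir, "predictions.csv"),
                   row.names = FALSE)
  invisible(dir)
}
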