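#' Run the full instar-determination pipeline on a measurement table
#'
#' Executes one clustering backend, then the whole validation battery:
#' per-instar summary statistics, Brooks-Dyar and Crosby indices, log-linear
#' growth regression per feature, size-frequency overlap analysis and the
#' 2-component PCA projection. If the table carries generator truth labels,
#' the adjusted Rand index against the truth is reported as well.
#'
#' Method defaults follow the published analysis: OPTICS at `minPts = 5`
#' with automatic threshold extraction (`eps_cl` = the 4-NN knee estimate,
#' i.e. k = minPts - 1), DBSCAN at `eps = 0.04`, `minPts = 4`, k-means at
#' `k = 4`, and BIC selection over 1..9 components and all six covariance
#' families for the mixture backend.
#'
#' @param table a `measurement_table`.
#' @param method one of `"optics"`, `"dbscan"`, `"kmeans"`, `"gmm"`.
#' @param params named list of method parameters overriding the defaults
#'   (`minPts`, `eps_cl`, `xi`, `extraction` for optics; `eps`, `minPts` for
#'   dbscan; `k`, `n_starts` for kmeans; `k_range`, `families` for gmm).
#' @param seed integer seed recorded in the report and used by the
#'   stochastic backends.
#' @param output_dir optional directory; when given, the labeled partition
#'   CSV, the Table-1-shaped summary TSV and the JSON report are written
#'   there.
#' @return A `run_report` list: `method`, `params`, `seed`, `K`,
#'   `cluster_sizes`, `n_noise`, `partition`, `summary`, `regressions`
#'   (per feature), `crosby_pass`, `frequency_overlap`, `pca_variance`,
#'   `ari_truth` (or `NA`), `validated` (FALSE with a `notice` when fewer
#'   than 2 instars were found), and `files` (manifest of written outputs).
#' @export
run_pipeline <- function(table, method = c("optics", "dbscan", "kmeans",
                                           "gmm"),
                         params = list(), seed = 1L, output_dir = NULL) {
  method <- match.arg(method)
  defaults <- switch(method,
    optics = list(minPts = 5L, eps = Inf, extraction = "threshold",
                  eps_cl = NULL, xi = 0.05),
    dbscan = list(eps = 0.04, minPts = 4L),
    kmeans = list(k = 4L, n_starts = 10L),
    gmm = list(k_range = 1:9, families = names(gmm_families())))
  params <- utils::modifyList(defaults, params)
  extras <- list()
  part <- switch(method,
    optics = {
      res <- optics_order(table, minPts = params$minPts, eps = params$eps)
      if (params$extraction == "threshold") {
        eps_cl <- params$eps_cl
        if (is.null(eps_cl)) {
          # the largest defined core-distance radius: the smallest threshold
          # at which no core point of the ordering is lost to noise, so the
          # extraction cuts only at the cluster-separating reachability peaks
          eps_cl <- max(knn_distances(table,
                                      max(params$minPts - 1L, 1L))$distances)
        }
        extras$eps_cl <- eps_cl
        extract_clusters_reachability(res, table, eps_cl)
      } else {
        extract_clusters_xi(res, table, xi = params$xi)$partition
      }
    },
    dbscan = dbscan_cluster(table, eps = params$eps, minPts = params$minPts),
    kmeans = kmeans_lloyd(table, k = params$k, seed = seed,
                          n_starts = params$n_starts)$partition,
    gmm = {
      sel <- bic_select(table, k_range = params$k_range,
                        families = params$families, seed = seed)
      extras$best_k <- sel$best_k
      extras$best_family <- sel$best_family
      sel$partition
    })

  report <- list(method = method, params = params, seed = as.integer(seed),
                 derived = extras, K = part$K,
                 cluster_sizes = unname(cluster_sizes(part)),
                 n_noise = sum(partition_labels(part) == 0L),
                 partition = part,
                 ari_truth = if (all(is.na(table$instar))) NA_real_ else
                   adjusted_rand(part, generated_truth(table)))
  if (part$K < 2L) {
    report$validated <- FALSE
    report$notice <- paste0("only ", part$K, " cluster(s) found; ",
                            "instar validation requires at least 2")
  } else {
    report$validated <- TRUE
    report$summary <- summarize_instars(table, part)
    report$regressions <- lapply(
      stats::setNames(feature_columns(), feature_columns()),
      function(f) dyar_regression(table, part, f))
    report$crosby_pass <- if (part$K >= 3L) {
      all(vapply(feature_columns(), function(f) {
        d <- report$summary[report$summary$feature == f, "dyar"]
        crosby_indices(d[!is.na(d)])$pass
      }, logical(1)))
    } else NA
    freq <- frequency_analysis(table, part)
    report$frequency_overlap <- freq$any_overlap
    report$pca_variance <- pca_projection(table)$variance_explained
  }
  class(report) <- "run_report"
  if (!is.null(output_dir)) {
    report$files <- write_run_report(report, table, output_dir)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("instar pipeline run:", x$method, " seed =", x$seed, "\n")
  cat("K =", x$K, " sizes:", paste(x$cluster_sizes, collapse = ", "),
      " noise:", x$n_noise, "\n")
  if (!is.na(x$ari_truth)) cat("ARI vs generated truth:",
                               format(x$ari_truth, digits = 4), "\n")
  if (isTRUE(x$validated)) {
    for (f in names(x$regressions)) print(x$regressions[[f]])
    cat("Crosby rule pass (|C| < 0.10):", x$crosby_pass,
        " frequency overlap:", x$frequency_overlap, "\n")
  } else {
    cat("validation skipped:", x$notice, "\n")
  }
  invisible(x)
}

# write partition CSV, summary TSV and JSON report; returns the manifest
write_run_report <- function(report, table, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(partition = file.path(output_dir,
                                   paste0(report$method, "_partition.csv")),
             summary = file.path(output_dir,
                                 paste0(report$method, "_summary.tsv")),
             report = file.path(output_dir,
                                paste0(report$method, "_report.json")))
  write_partition(table, report$partition, files[["partition"]])
  if (isTRUE(report$validated)) {
    utils::write.table(report$summary, files[["summary"]], sep = "\t",
                       row.names = FALSE, quote = FALSE)
  } else {
    files <- files[names(files) != "summary"]
  }
  json <- report
  json$partition <- partition_labels(report$partition)
  json$summary <- NULL
  json$files <- NULL
  json$regressions <- lapply(json$regressions, unclass)
  jsonlite::write_json(json, files[["report"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  files
}

#' Agreement matrix between clustering methods
#'
#' Runs several pipeline configurations on the same table and computes the
#' adjusted Rand index between every pair of resulting partitions (noise
#' treated as a class of its own). An ARI of 1 between two methods means
#' they produced identical instar clusters.
#'
#' @param table a `measurement_table`.
#' @param configs named list of at least 2 configs, each a list with
#'   `method` and optionally `params` (as in [run_pipeline()]).
#' @param seed integer seed shared by all runs.
#' @return List with `ari` (symmetric matrix) and `partitions`.
#' @export
compare_methods <- function(table, configs, seed = 1L) {
  stopifnot(length(configs) >= 2L)
  if (is.null(names(configs))) {
    names(configs) <- vapply(configs, `[[`, character(1), "method")
  }
  parts <- lapply(configs, function(cf) {
    run_pipeline(table, method = cf$method,
                 params = if (is.null(cf$params)) list() else cf$params,
                 seed = seed)$partition
  })
  m <- length(parts)
  ari <- matrix(1, m, m, dimnames = list(names(configs), names(configs)))
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      ari[i, j] <- ari[j, i] <- adjusted_rand(parts[[i]], parts[[j]])
    }
  }
  list(ari = ari, partitions = parts)
}
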