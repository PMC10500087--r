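# Delimited-file ingestion and result serialization.
#
# All inputs are header-ed delimited text (TSV by default) whose first column
# is the individual ID: exposure (ID, value), covariates (ID, one column per
# covariate), mediators (ID, one column per mediator), outcomes (ID, one
# column per graph). The mapping file has two columns (graph, mediator)
# assigning mediator columns to graphs, mirroring a probe-to-gene reference.

read_tsv_checked <- function(path, sep = "\t", what = "file") {
  if (!file.exists(path)) stop(what, " not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 1) stop(what, " is empty: ", path, call. = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop(what, " has duplicate individual IDs: ", path, call. = FALSE)
  }
  vals <- df[, -1, drop = FALSE]
  bad <- !vapply(vals, is.numeric, logical(1))
  if (any(bad)) {
    stop(what, " has non-numeric cells in column(s): ",
         paste(names(vals)[bad], collapse = ", "), call. = FALSE)
  }
  rownames(vals) <- ids
  vals
}

#' Read a mediation experiment from delimited files
#'
#' Joins the individuals present in every file (inner join on the ID column,
#' in the order of the exposure file), validates the design, and drops graphs
#' whose mediator columns are absent (with a warning).
#'
#' @param exposure_file,mediators_file,outcomes_file paths to delimited files
#'   with a header row and the individual ID as first column.
#' @param mapping_file two-column delimited file (graph, mediator) assigning
#'   mediator column names to outcome column names.
#' @param covariates_file optional covariate file (same layout).
#' @param sep field separator (tab by default).
#' @return a [mediation_design].
#' @export
read_experiment <- function(exposure_file, mediators_file, outcomes_file,
                            mapping_file, covariates_file = NULL,
                            sep = "\t") {
  expo <- read_tsv_checked(exposure_file, sep, "exposure file")
  med <- read_tsv_checked(mediators_file, sep, "mediator file")
  outc <- read_tsv_checked(outcomes_file, sep, "outcome file")
  cov <- if (!is.null(covariates_file)) {
    read_tsv_checked(covariates_file, sep, "covariate file")
  } else NULL
  map <- utils::read.table(mapping_file, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (ncol(map) < 2) {
    stop("mapping file needs two columns (graph, mediator)", call. = FALSE)
  }
  names(map)[1:2] <- c("graph", "mediator")

  ids <- rownames(expo)
  for (other in list(med, outc, cov)) {
    if (!is.null(other)) ids <- ids[ids %in% rownames(other)]
  }
  if (!length(ids)) {
    stop("no individuals shared across all input files", call. = FALSE)
  }
  dropped <- length(rownames(expo)) - length(ids)
  if (dropped > 0) {
    message(dropped, " individual(s) without complete data dropped")
  }
  mediation_design(
    exposure = expo[ids, 1],
    mediators = as.matrix(med[ids, , drop = FALSE]),
    outcomes = as.matrix(outc[ids, , drop = FALSE]),
    mapping = map,
    covariates = if (!is.null(cov)) as.matrix(cov[ids, , drop = FALSE])
  )
}

#' Write scan results and a discovery summary
#'
#' One row per graph with ids, dimensions, all computed p-values (scientific
#' notation, 6 significant digits), q-values, discovery flags and QQ columns;
#' followed (in a separate file) by a summary with discovery counts per
#' approach and their overlaps. Output is deterministic; an optional
#' timestamp header is off by default.
#'
#' @param scan a `"mediation_scan"`.
#' @param file path of the results TSV.
#' @param summary_file optional path of the summary text file.
#' @param timestamp include a timestamp header line.
#' @return invisibly, the results data frame as written.
#' @export
write_results <- function(scan, file, summary_file = NULL, timestamp = FALSE) {
  stopifnot(inherits(scan, "mediation_scan"))
  res <- scan$results
  if (!nrow(res)) stop("empty result set", call. = FALSE)
  out <- res
  pcols <- grep("^[pq]_", names(out), value = TRUE)
  for (cn in pcols) out[[cn]] <- format(out[[cn]], digits = 6, scientific = TRUE)
  qq <- qq_data(scan)
  for (ap in unique(qq$approach)) {
    sub <- qq[qq$approach == ap, ]
    out[[paste0("qq_expected_", ap)]] <- NA_real_
    out[[paste0("qq_observed_", ap)]] <- NA_real_
    idx <- match(sub$graph, out$graph)
    out[[paste0("qq_expected_", ap)]][idx] <- round(sub$expected, 6)
    out[[paste0("qq_observed_", ap)]][idx] <- round(sub$observed, 6)
  }
  con <- file(file, "w")
  on.exit(close(con))
  if (timestamp) {
    writeLines(paste0("# written ", format(Sys.time(), usetz = TRUE)), con)
  }
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(summary_file)) {
    s <- summary(scan)
    lines <- c(
      sprintf("graphs\t%d", s$g),
      sprintf("individuals\t%d", s$n),
      sprintf("failed_graphs\t%d", s$n_failed),
      sprintf("fdr_cutoff\t%g", s$settings$fdr_cutoff),
      vapply(names(s$discoveries), function(k) {
        sprintf("discoveries_%s\t%d", k, s$discoveries[[k]])
      }, character(1))
    )
    if (length(s$discoveries) > 1) {
      nm <- names(s$discoveries)
      for (i in seq_along(nm)) {
        for (j in seq_along(nm)) {
          if (i < j) {
            lines <- c(lines, sprintf("overlap_%s_%s\t%d", nm[i], nm[j],
                                      s$overlap[i, j]))
          }
        }
      }
    }
    writeLines(lines, summary_file)
  }
  invisible(out)
}

#' Write a small demonstration experiment to delimited files
#'
#' Generates a toy experiment (10 individuals, 3 graphs with 1, 2 and 3
#' mediators) and writes the five input files consumed by
#' [read_experiment]. Used by the bundled tests and the command-line
#' `fixtures` subcommand.
#'
#' @param dir output directory (created if missing).
#' @param seed integer seed.
#' @param n individuals.
#' @return invisibly, the named vector of file paths.
#' @export
write_demo_experiment <- function(dir, seed = 1, n = 10) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  ids <- sprintf("ind%02d", seq_len(n))
  S <- round(stats::rnorm(n), 4)
  X <- matrix(round(stats::rnorm(n * 2), 4), n, 2,
              dimnames = list(NULL, c("age", "sex")))
  m_per <- c(gene1 = 1, gene2 = 2, gene3 = 3)
  med_names <- unlist(lapply(names(m_per), function(g) {
    paste0(g, "_cpg", seq_len(m_per[[g]]))
  }))
  M <- matrix(round(stats::rnorm(n * length(med_names)), 4), n,
              dimnames = list(NULL, med_names))
  Y <- matrix(round(stats::rnorm(n * 3), 4), n,
              dimnames = list(NULL, names(m_per)))
  map <- data.frame(graph = rep(names(m_per), m_per), mediator = med_names)
  paths <- c(exposure = file.path(dir, "exposure.tsv"),
             covariates = file.path(dir, "covariates.tsv"),
             mediators = file.path(dir, "mediators.tsv"),
             outcomes = file.path(dir, "outcomes.tsv"),
             mapping = file.path(dir, "mapping.tsv"))
  wr <- function(mat, path) {
    df <- data.frame(id = ids, mat, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr(data.frame(smoking = S), paths["exposure"])
  wr(X, paths["covariates"])
  wr(M, paths["mediators"])
  wr(Y, paths["outcomes"])
  utils::write.table(map, paths["mapping"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
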