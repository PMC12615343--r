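#' Read an amplitude-sweep export
#'
#' Reads a delimited rheometer export (CSV, or TSV by extension) into a
#' [strain_sweep()].  Column names are configurable; strains in percent are
#' converted to fractions at ingest (all internal strains are fractions).
#' Rows with non-positive moduli are dropped with a message.
#'
#' @param path file path.
#' @param column_map named character vector mapping internal names
#'   (`strain`, `g_prime`, `g_double_prime`) to file column names.
#' @param percent if TRUE (default) the strain column is in percent.
#' @param frequency sweep frequency metadata, Hz.
#' @return A [strain_sweep()].
#' @export
read_sweep_csv <- function(path,
                           column_map = c(strain = "strain_pct",
                                          g_prime = "g_prime_pa",
                                          g_double_prime = "g_loss_pa"),
                           percent = TRUE, frequency = 1) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "txt")) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- column_map[c("strain", "g_prime", "g_double_prime")]
  miss <- setdiff(unname(need), names(df))
  if (length(miss) > 0)
    stop("missing column(s) in ", basename(path), ": ",
         paste(miss, collapse = ", "))
  strain <- df[[need[["strain"]]]]
  gp <- df[[need[["g_prime"]]]]
  gpp <- df[[need[["g_double_prime"]]]]
  bad <- !is.finite(gp) | gp <= 0 | !is.finite(gpp) | gpp <= 0 |
    !is.finite(strain) | strain <= 0
  if (any(bad))
    message(sum(bad), " row(s) with non-positive values dropped from ",
            basename(path))
  strain <- strain[!bad]; gp <- gp[!bad]; gpp <- gpp[!bad]
  if (length(strain) < 8)
    stop("fewer than 8 valid rows in ", basename(path))
  ord <- order(strain)
  strain_sweep(strain[ord], gp[ord], gpp[ord], frequency = frequency,
               percent = percent)
}

#' Write a sweep to CSV
#'
#' Inverse of [read_sweep_csv()] with the default column names (strain in
#' percent).
#'
#' @param sweep a [strain_sweep()].
#' @param path output path.
#' @export
write_sweep_csv <- function(sweep, path) {
  stopifnot(inherits(sweep, "strain_sweep"))
  utils::write.csv(data.frame(strain_pct = sweep$strain * 100,
                              g_prime_pa = sweep$g_prime,
                              g_loss_pa = sweep$g_double_prime),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write fitted parameters, one row per ink
#'
#' @param fits named list of [fit_sweep()] results (or [rheo_params()]
#'   objects); names are ink ids.
#' @param path output CSV path.
#' @return The table written, invisibly.
#' @export
write_params_csv <- function(fits, path) {
  rows <- lapply(names(fits), function(id) {
    f <- fits[[id]]
    p <- if (inherits(f, "sweep_fit")) f$params else f
    if (is.null(p))
      return(data.frame(ink_id = id, g0 = NA, tan_delta = NA,
                        gamma_cr1 = NA, gamma_cr2 = NA, n1 = NA, n2 = NA,
                        a = NA, sigma_y = NA, fit_r2_log = NA,
                        converged = FALSE))
    data.frame(ink_id = id, g0 = p$g0, tan_delta = p$tan_delta,
               gamma_cr1 = p$gamma_cr1, gamma_cr2 = p$gamma_cr2,
               n1 = p$n1, n2 = p$n2, a = p$a, sigma_y = p$sigma_y,
               fit_r2_log = p$fit_r2_log,
               converged = if (inherits(f, "sweep_fit")) f$converged else TRUE)
  })
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}

#' Read an ink table CSV into validated records
#'
#' @param path CSV with columns `ink_id`, `ink_class` and any of the
#'   numeric fields of [ink_records()].
#' @return An [ink_records()] table.
#' @export
read_ink_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ink_records(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_ink_table
#' @param records an [ink_records()] table.
#' @export
write_ink_table <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Assembles reader options, a per-class [filter_spec()] map, a
#' [pipeline_config()], fit and statistics options and the global seed from
#' one YAML file.  Unknown keys are kept verbatim so the configuration
#' round-trips.
#'
#' @param path YAML path.
#' @return list of class `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  pc <- do.call(pipeline_config, y$pipeline %||% list())
  filters <- list()
  for (cl in names(y$filters %||% list())) {
    f <- y$filters[[cl]]
    filters[[cl]] <- if (is.character(f)) filter_spec_from_yaml(f)
    else .filter_spec_from_list(f)
  }
  structure(list(paths = y$paths %||% list(),
                 filters = filters, pipeline = pc,
                 fit = y$fit %||% list(), stats = y$stats %||% list(),
                 seed = y$seed %||% 1, raw = y),
            class = "run_config")
}

## md5 of a serialized R object, used to stamp artifacts with their config
.config_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf)
  unname(tools::md5sum(tf))
}
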