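#' Write a spike record
#'
#' Two-column plain text (`time_ms`, `afferent_id`; the postsynaptic
#' neuron uses id -1), or an RDS binary container holding the named
#' datasets.  Both formats round-trip exactly through [read_spikes()].
#'
#' @param time spike times (ms)
#' @param afferent afferent ids (use -1 for postsynaptic spikes)
#' @param path output file
#' @param format `"text"` or `"rds"`
#' @return `path`, invisibly
#' @export
write_spikes <- function(time, afferent, path, format = c("text", "rds")) {
  format <- match.arg(format)
  stopifnot(length(time) == length(afferent))
  if (format == "text") {
    utils::write.table(
      data.frame(time_ms = format(time, digits = 15, scientific = FALSE,
                                  trim = TRUE),
                 afferent_id = as.integer(afferent)),
      path, quote = FALSE, row.names = FALSE, sep = "\t")
  } else {
    saveRDS(list(time_ms = time, afferent_id = as.integer(afferent)), path,
            compress = "gzip")
  }
  invisible(path)
}

#' Read a spike record
#'
#' @param path file written by [write_spikes()]
#' @param format `"text"` or `"rds"`; guessed from the extension by default
#' @return list with `time` (ms) and `afferent`
#' @export
read_spikes <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.rds$", path, ignore.case = TRUE)) "rds" else "text"
  if (format == "rds") {
    x <- readRDS(path)
    return(list(time = x$time_ms, afferent = x$afferent_id))
  }
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = c("numeric", "integer"))
  list(time = d$time_ms, afferent = d$afferent_id)
}

#' Write a weight table
#'
#' Columnar plain text: afferent, population, group, weight.
#'
#' @param arch an [input_architecture()]
#' @param w weight vector
#' @param path output file
#' @return `path`, invisibly
#' @export
write_weights <- function(arch, w, path) {
  tab <- weight_table(arch, w)
  tab$weight <- format(tab$weight, digits = 15, trim = TRUE)
  utils::write.table(tab, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Read a weight table
#'
#' @param path file written by [write_weights()]
#' @return data.frame with afferent, population, group, weight
#' @export
read_weights <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("integer", "integer", "integer", "numeric"))
}

#' Export per-group rate time series
#'
#' Columnar text: time_ms, then one rate column per signal group (Hz).
#'
#' @param y OU matrix (rows = dT updates, columns = groups), e.g. from
#'   [generate_natural_raster()]
#' @param rates a [rate_params()]
#' @param pop `"exc"` or `"inh"`
#' @param path output file
#' @param dT update step (ms)
#' @return `path`, invisibly
#' @export
write_group_rates <- function(y, rates, pop, path, dT = rates$dT) {
  r <- apply(y, 2, group_rate, pop = pop, params = rates)
  d <- data.frame(time_ms = seq_len(nrow(y)) * dT, r)
  names(d) <- c("time_ms", paste0("group_", seq_len(ncol(y))))
  utils::write.table(d, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}
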