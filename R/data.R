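#' Sweep dataset container
#'
#' A \code{sweep_dataset} holds a named list of cells, a metadata table and,
#' for synthetic data, the generating ground truth. Each cell is a list with
#' \code{cell_id}, \code{channel_type}, \code{temperature} (degrees C) and
#' \code{sweeps}; each sweep record has \code{protocol}, \code{sweep_index},
#' \code{repetition}, \code{times} (ms) and \code{current}.
#'
#' @param cells named list of cell records
#' @param metadata data.frame with columns cell_id, channel_type,
#'   temperature_C (built from the cells when omitted)
#' @param truth optional ground-truth object (see
#'   \code{\link{simulate_population}})
#' @param processed logical; TRUE after \code{\link{run_pipeline}}
#' @return a \code{sweep_dataset} object
#' @export
sweep_dataset <- function(cells, metadata = NULL, truth = NULL, processed = FALSE) {
  if (is.null(names(cells)) && length(cells)) {
    names(cells) <- vapply(cells, `[[`, character(1), "cell_id")
  }
  if (is.null(metadata)) {
    metadata <- data.frame(
      cell_id = vapply(cells, `[[`, character(1), "cell_id"),
      channel_type = vapply(cells, `[[`, character(1), "channel_type"),
      temperature_C = vapply(cells, `[[`, numeric(1), "temperature")
    )
    rownames(metadata) <- NULL
  }
  structure(list(cells = cells, metadata = metadata, truth = truth,
                 processed = processed),
            class = "sweep_dataset")
}

#' @export
print.sweep_dataset <- function(x, ...) {
  n_sweeps <- sum(vapply(x$cells, function(c) length(c$sweeps), integer(1)))
  cat(sprintf("<sweep_dataset> %d cells, %d sweeps%s%s\n",
              length(x$cells), n_sweeps,
              if (x$processed) ", processed" else ", raw",
              if (!is.null(x$truth)) ", with ground truth" else ""))
  invisible(x)
}

sweep_voltage_trace <- function(s, recovery_test_ms = NULL) {
  if (is.null(recovery_test_ms) && s$protocol == "recovery") {
    gap <- 50 + 150 * (s$sweep_index - 1)
    dt <- stats::median(diff(s$times))
    recovery_test_ms <- round(max(s$times) + dt) - 1700 - gap
  }
  proto <- build_protocol(s$protocol,
                          overrides = list(recovery_test_ms = recovery_test_ms))[[s$sweep_index]]
  idx <- findInterval(s$times, proto$segments$t_start)
  idx[idx < 1L] <- 1L
  idx[idx > nrow(proto$segments)] <- nrow(proto$segments)
  proto$segments$voltage[idx]
}

#' Write a sweep dataset to a directory of delimited text files
#'
#' Produces \code{metadata.csv}, one \code{cells/<cell_id>.csv} per cell
#' (columns protocol, sweep_index, repetition, t_ms, voltage_mV, current)
#' and, when ground truth is present, \code{truth_cells.csv} and
#' \code{truth_artifacts.csv}.
#'
#' @param dataset a \code{sweep_dataset}
#' @param path output directory (created if needed)
#' @return \code{path}, invisibly
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "sweep_dataset"))
  dir.create(file.path(path, "cells"), recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(dataset$metadata, file.path(path, "metadata.csv"))
  for (cell in dataset$cells) {
    tabs <- lapply(cell$sweeps, function(s) {
      data.table::data.table(
        protocol = s$protocol, sweep_index = s$sweep_index,
        repetition = s$repetition, t_ms = s$times,
        voltage_mV = sweep_voltage_trace(s), current = s$current
      )
    })
    data.table::fwrite(data.table::rbindlist(tabs),
                       file.path(path, "cells", paste0(cell$cell_id, ".csv")))
  }
  if (!is.null(dataset$truth)) {
    data.table::fwrite(dataset$truth$cells, file.path(path, "truth_cells.csv"))
    data.table::fwrite(dataset$truth$artifacts, file.path(path, "truth_artifacts.csv"))
  }
  invisible(path)
}

#' Read a sweep dataset written by \code{\link{write_dataset}}
#'
#' @param path directory containing metadata.csv and cells/
#' @return a \code{sweep_dataset}
#' @export
read_dataset <- function(path) {
  meta_file <- file.path(path, "metadata.csv")
  if (!file.exists(meta_file)) stop("missing metadata.csv in ", path, call. = FALSE)
  meta <- as.data.frame(data.table::fread(meta_file))
  needed <- c("cell_id", "channel_type", "temperature_C")
  missing_cols <- setdiff(needed, names(meta))
  if (length(missing_cols)) {
    stop("metadata.csv lacks column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cells <- list()
  for (r in seq_len(nrow(meta))) {
    cid <- as.character(meta$cell_id[r])
    f <- file.path(path, "cells", paste0(cid, ".csv"))
    if (!file.exists(f)) stop("missing cell file for ", cid, call. = FALSE)
    tab <- data.table::fread(f)
    needed_sw <- c("protocol", "sweep_index", "repetition", "t_ms", "current")
    miss <- setdiff(needed_sw, names(tab))
    if (length(miss)) stop("cell file ", cid, " lacks column(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    key <- paste(tab$protocol, tab$sweep_index, tab$repetition)
    sweeps <- lapply(split(seq_len(nrow(tab)), key), function(i) {
      list(protocol = tab$protocol[i[1]],
           sweep_index = as.integer(tab$sweep_index[i[1]]),
           repetition = as.integer(tab$repetition[i[1]]),
           times = tab$t_ms[i], current = tab$current[i])
    })
    names(sweeps) <- NULL
    cells[[cid]] <- list(cell_id = cid, channel_type = meta$channel_type[r],
                         temperature = meta$temperature_C[r], sweeps = sweeps)
  }
  truth <- NULL
  tf <- file.path(path, "truth_cells.csv")
  if (file.exists(tf)) {
    truth <- list(cells = as.data.frame(data.table::fread(tf)),
                  artifacts = as.data.frame(data.table::fread(file.path(path, "truth_artifacts.csv"))))
  }
  sweep_dataset(cells, metadata = meta, truth = truth)
}
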