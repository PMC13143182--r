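#' NWB reader stub
#'
#' Raw recordings distributed as NWB containers are not parsed by this
#' package; convert them to the delimited sweep format documented in
#' \code{\link{write_dataset}} first.
#'
#' @param path path to an .nwb file
#' @return never returns
#' @export
read_nwb_dataset <- function(path) {
  stop("NWB containers are not supported; export the sweeps to the ",
       "delimited format described in ?write_dataset and use read_dataset()",
       call. = FALSE)
}

#' Serialize a fitted deep gating model to a JSON archive
#'
#' Writes a single text-JSON file holding the layer sizes, every weight and
#' bias array, Omega, sigma and the model configuration.
#'
#' @param model a \code{deep_gating_model}
#' @param path output file
#' @param Omega optional covariance to store (defaults to the model's)
#' @return \code{path}, invisibly
#' @export
save_deep_model <- function(model, path, Omega = model$Omega) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("the jsonlite package is required for model serialization", call. = FALSE)
  }
  obj <- list(
    format = "hhmix_deep_gating_model",
    version = 1L,
    config = model$config,
    lambda = model$lambda,
    sigma = model$sigma,
    Omega = as.matrix(Omega),
    nets = lapply(model$nets, function(net) {
      list(sizes = net$sizes, head = net$head, W = net$W, b = net$b)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Load a deep gating model written by \code{\link{save_deep_model}}
#'
#' @param path archive file
#' @return list(model, Omega)
#' @export
load_deep_model <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("the jsonlite package is required for model serialization", call. = FALSE)
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "hhmix_deep_gating_model")) {
    stop("not a deep gating model archive: ", path, call. = FALSE)
  }
  cfg <- obj$config
  model <- deep_gating_model(
    n_onehot = cfg$n_onehot, hidden = unlist(cfg$hidden),
    tau_scale = cfg$tau_scale, v_scale = cfg$v_scale, sigma = obj$sigma,
    lambda = obj$lambda, powers = unlist(cfg$powers), E = cfg$E,
    V_max = cfg$V_max, eta_temp_in_gating = cfg$eta_temp_in_gating)
  as_mat <- function(x, nr, nc) {
    if (is.list(x)) x <- do.call(rbind, lapply(x, unlist))
    matrix(as.numeric(t(x)), nrow = nr, ncol = nc, byrow = TRUE)
  }
  for (nm in names(model$nets)) {
    saved <- obj$nets[[nm]]
    net <- model$nets[[nm]]
    for (l in seq_along(net$W)) {
      net$W[[l]] <- as_mat(saved$W[[l]], nrow(net$W[[l]]), ncol(net$W[[l]]))
      net$b[[l]] <- as.numeric(unlist(saved$b[[l]]))
    }
    model$nets[[nm]] <- net
  }
  d <- nrow(as.matrix(model$Omega))
  model$Omega <- as_mat(obj$Omega, d, d)
  list(model = model, Omega = model$Omega)
}
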