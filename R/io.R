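# Serialization: JSON array container for networks and interval parameters,
# dataset persistence, experiment manifests, and simple plot/CSV emitters.

layer_to_list <- function(layer) {
  list(type = layer$type, activation = layer$activation,
       dim = as.integer(dim(layer$W) %||% c(nrow(layer$W), ncol(layer$W))),
       W = as.numeric(layer$W), b = as.numeric(layer$b))
}

layer_from_list <- function(l) {
  W <- if (l$type == "conv1d") {
    array(l$W, dim = l$dim)
  } else {
    matrix(l$W, l$dim[1], l$dim[2])
  }
  if (l$type == "conv1d") {
    conv1d_layer(W, l$b, activation = l$activation)
  } else {
    dense_layer(W, l$b, activation = l$activation)
  }
}

#' Write a network (with optional interval parameters) to a JSON container
#'
#' Stores one named group per layer with entries `W`, `b` and — for interval
#' networks — `W_lo`, `W_hi`, `b_lo`, `b_hi`, plus the dropout configuration,
#' interval layer set, and tightness parameter.
#'
#' @param net A [prediction_network()] or `interval_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  if (inherits(net, "interval_network")) {
    base <- net$base
    layers <- lapply(seq_along(base$layers), function(i) {
      l <- layer_to_list(base$layers[[i]])
      p <- net$params[[i]]
      l$W_lo <- as.numeric(p$W_lo)
      l$W_hi <- as.numeric(p$W_hi)
      l$b_lo <- as.numeric(p$b_lo)
      l$b_hi <- as.numeric(p$b_hi)
      l
    })
    obj <- list(kind = "interval_network", layers = layers,
                dropout_sites = base$dropout_sites,
                dropout_rate = base$dropout_rate,
                interval_layers = net$interval_layers, beta = net$beta)
  } else if (inherits(net, "prediction_network")) {
    obj <- list(kind = "prediction_network",
                layers = lapply(net$layers, layer_to_list),
                dropout_sites = net$dropout_sites,
                dropout_rate = net$dropout_rate)
  } else {
    stop_contract("`net` must be a prediction_network or interval_network")
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a network from a JSON container
#'
#' @param path File written by [write_network()].
#' @return A [prediction_network()] or `interval_network`.
#' @export
read_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  layers <- lapply(obj$layers, layer_from_list)
  net <- prediction_network(layers,
                            dropout_sites = obj$dropout_sites %||% integer(0),
                            dropout_rate = obj$dropout_rate %||% 0)
  if (identical(obj$kind, "interval_network")) {
    inn <- wrap_network(net, interval_layers = obj$interval_layers,
                        init_width = 0, eps0 = 0,
                        beta = obj$beta %||% NA_real_)
    for (i in seq_along(obj$layers)) {
      l <- obj$layers[[i]]
      d <- dim(net$layers[[i]]$W)
      shape <- function(v) if (length(d) == 3) array(v, dim = d) else matrix(v, d[1], d[2])
      inn$params[[i]] <- list(W_lo = shape(l$W_lo), W_hi = shape(l$W_hi),
                              b_lo = as.numeric(l$b_lo),
                              b_hi = as.numeric(l$b_hi))
    }
    validate_interval_network(inn)
    inn
  } else {
    net
  }
}

#' Save / load a dataset
#'
#' The arrays are stored as an RDS file; a JSON sidecar (`<path>.json`)
#' records the problem parameters, sampler settings and seed needed to
#' regenerate it.
#'
#' @param ds A [make_dataset()] sample set.
#' @param path Output path for the RDS file.
#' @return `path`, invisibly.
#' @export
save_dataset <- function(ds, path) {
  saveRDS(ds, path)
  sidecar <- list(n = ds$problem$n, nu = ds$problem$nu,
                  noise_mode = ds$problem$noise_mode,
                  sigma = ds$problem$sigma,
                  n_total = ncol(ds$signals),
                  split_sizes = as.list(table(ds$split)),
                  jump_count_range = ds$jump_count_range,
                  height_range = ds$height_range, seed = ds$seed)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) {
  readRDS(path)
}

#' Write an experiment manifest
#'
#' Records the full configuration, seed, and package/R versions, enough to
#' re-run the experiment exactly.
#'
#' @param cfg An [experiment_config()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(cfg, path) {
  cfg_plain <- unclass(cfg)
  cfg_plain$attack <- unclass(cfg_plain$attack)
  obj <- list(
    config = cfg_plain,
    package_version = as.character(utils::packageVersion("innuq")),
    r_version = R.version.string,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Plot a noise sweep
#'
#' Mean uncertainty against the noise level, one line per UQ method.
#'
#' @param sweep Data frame from [run_noise_sweep()].
#' @param path Optional PDF output path; `NULL` plots to the active device.
#' @return `NULL`, invisibly.
#' @export
plot_noise_sweep <- function(sweep, path = NULL) {
  if (!is.null(path)) {
    grDevices::pdf(path, width = 6, height = 4)
    on.exit(grDevices::dev.off())
  }
  methods <- unique(sweep$method)
  cols <- seq_along(methods)
  graphics::plot(NULL, xlim = range(sweep$sigma),
                 ylim = range(sweep$mean_uncertainty),
                 xlab = expression(sigma), ylab = "mean uncertainty")
  for (i in seq_along(methods)) {
    s <- sweep[sweep$method == methods[i], ]
    graphics::lines(s$sigma, s$mean_uncertainty, col = cols[i], type = "b",
                    pch = 19)
  }
  graphics::legend("topleft", legend = methods, col = cols, lty = 1, pch = 19,
                   bty = "n")
  invisible(NULL)
}

#' Plot a directionality-accuracy table
#'
#' Directionality accuracy per ratio bin (left axis) with the relative
#' component frequency per bin (right axis).
#'
#' @param da Data frame from [directionality_accuracy()].
#' @param path Optional PDF output path.
#' @return `NULL`, invisibly.
#' @export
plot_directionality <- function(da, path = NULL) {
  if (!is.null(path)) {
    grDevices::pdf(path, width = 6, height = 4)
    on.exit(grDevices::dev.off())
  }
  mid <- sqrt(da$bin_lo * da$bin_hi)
  keep <- da$count > 0
  graphics::plot(mid[keep], da$da[keep], log = "x", type = "b", pch = 19,
                 xlab = "directionality ratio", ylab = "directionality accuracy",
                 ylim = c(0, 1))
  graphics::abline(h = 0.5, lty = 2)
  graphics::par(new = TRUE)
  graphics::plot(mid[keep], da$freq[keep], log = "x", type = "h", col = "blue",
                 axes = FALSE, xlab = "", ylab = "")
  graphics::axis(4, col.axis = "blue")
  graphics::mtext("relative frequency", side = 4, line = 2, col = "blue",
                  cex = 0.8)
  invisible(NULL)
}
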