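# Bundle serialisation: one versioned single-file archive per trained model,
# written atomically (write to a temporary file, then rename), so a partial
# write never leaves a valid-looking bundle behind.

BUNDLE_VERSION <- 1L

atomic_save <- function(object, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  saveRDS(object, tmp)
  if (!file.rename(tmp, path)) {
    stop_pivae("could not write ", path, class = "pivae_io_error")
  }
  invisible(path)
}

#' Save and load trained model bundles
#'
#' A bundle is a single-file versioned archive of everything stage-2
#' inference needs (feature map, decoder, coefficient bank, scaling) plus
#' the encoder and provenance metadata (stage-1 prior name, seed,
#' configuration hash). Loading validates the format version and the
#' parameter shapes; a round trip reproduces `simulate()` output bitwise.
#'
#' @param object A fitted [pivae()] or [gridvae()] model.
#' @param path Bundle file path.
#' @return `save_pivae` invisibly returns the manifest (a list);
#'   `load_pivae` returns the model.
#' @export
save_pivae <- function(object, path) {
  stopifnot(inherits(object, "pivae") || inherits(object, "gridvae"))
  manifest <- list(format = "pivae_bundle", version = BUNDLE_VERSION,
                   class = class(object)[1],
                   prior = object$meta$prior %||% NA_character_,
                   seed = object$meta$seed,
                   config_hash = object$meta$config_hash,
                   latent_dim = object$latent_dim,
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  atomic_save(list(manifest = manifest, model = unclass(object)), path)
  invisible(manifest)
}

#' @rdname save_pivae
#' @export
load_pivae <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) NULL)
  if (is.null(obj) || !is.list(obj) || !identical(obj$manifest$format,
                                                  "pivae_bundle")) {
    stop_pivae("not a valid model bundle: ", path, class = "pivae_io_error")
  }
  if (!identical(obj$manifest$version, BUNDLE_VERSION)) {
    stop_pivae("unknown bundle format version: ", obj$manifest$version,
               class = "pivae_version_error")
  }
  model <- structure(obj$model, class = obj$manifest$class)
  validate_bundle(model)
  model
}

validate_bundle <- function(model) {
  ok <- TRUE
  chk <- function(x) all(vapply(x, function(v) all(is.finite(v)), logical(1)))
  if (inherits(model, "pivae")) {
    F_dim <- ncol(model$beta)
    dec_out <- model$decoder$sizes[length(model$decoder$sizes)]
    enc_in <- model$encoder$sizes[1]
    enc_out <- model$encoder$sizes[length(model$encoder$sizes)]
    ok <- dec_out == F_dim && enc_in == F_dim &&
      enc_out == 2L * model$latent_dim &&
      model$decoder$sizes[1] == model$latent_dim &&
      chk(model$decoder$W) && chk(model$encoder$W) && all(is.finite(model$beta))
    if (ok && model$feature_map$kind == "kernel") {
      ok <- model$feature_map$net$sizes[length(model$feature_map$net$sizes)] ==
        F_dim * model$P && all(is.finite(model$feature_map$centres))
    }
  } else if (inherits(model, "gridvae")) {
    G <- length(model$grid)
    ok <- model$decoder$sizes[length(model$decoder$sizes)] == G &&
      model$encoder$sizes[1] == G && chk(model$decoder$W) && chk(model$encoder$W)
  }
  if (!ok) {
    stop_pivae("bundle failed integrity checks (parameter shapes or finiteness)",
               class = "pivae_integrity_error")
  }
  invisible(model)
}
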