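# Model bundle: a directory holding model.json (all parameters needed to
# reproduce predictions) and run_config.json. Everything is plain text so a
# bundle is diffable and byte-stable for identical seeds and inputs.

BUNDLE_FORMAT_VERSION <- "1.0"

phmm_to_list <- function(h) {
  list(length = h$length,
       match_emissions = unname(h$match_emissions),
       insert_emissions = unname(h$insert_emissions),
       transitions = h$transitions,
       null_model = unname(h$null_model),
       pseudocount = h$pseudocount,
       n_train = h$n_train)
}

phmm_from_list <- function(x) {
  m <- list(length = x$length,
            match_emissions = matrix(unlist(x$match_emissions),
                                     nrow = x$length, byrow = TRUE,
                                     dimnames = list(NULL, AA_SYMBOLS)),
            insert_emissions = stats::setNames(unlist(x$insert_emissions),
                                               AA_SYMBOLS),
            transitions = x$transitions,
            null_model = stats::setNames(unlist(x$null_model), AA_SYMBOLS),
            pseudocount = x$pseudocount,
            n_train = x$n_train)
  class(m) <- "profile_hmm"
  m
}

#' Save a two-layer model bundle to a directory
#'
#' @param model A \code{two_layer_model}.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sl <- model$second_layer
  payload <- list(
    format_version = BUNDLE_FORMAT_VERSION,
    w = model$w,
    scheme = as.list(model$scheme),
    tree = mdd_tree_to_list(model$tree),
    hmms = lapply(model$hmms, function(h)
      list(leaf_id = h$leaf_id, threshold = h$threshold,
           phmm = phmm_to_list(h$model))),
    second_layer = list(C = sl$C, gamma = sl$gamma,
                        SV = unname(sl$SV), coefs = sl$coefs, rho = sl$rho,
                        flip = sl$flip, platt = sl$platt,
                        prob_threshold = sl$prob_threshold),
    metadata = model$metadata)
  jsonlite::write_json(payload, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- model$config
  cfg$scheme <- as.list(cfg$scheme)
  jsonlite::write_json(unclass(cfg), file.path(dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load a two-layer model bundle
#'
#' @param dir Bundle directory written by \code{\link{save_model}}.
#' @return A \code{two_layer_model}.
#' @export
load_model <- function(dir) {
  mpath <- file.path(dir, "model.json")
  if (!file.exists(mpath)) stop("not a model bundle (missing model.json): ", dir)
  x <- jsonlite::read_json(mpath, simplifyVector = FALSE)
  if (!identical(x$format_version, BUNDLE_FORMAT_VERSION))
    stop("model bundle format version ", x$format_version,
         " is not supported (expected ", BUNDLE_FORMAT_VERSION, ")")
  scheme <- unlist(x$scheme)
  hmms <- lapply(x$hmms, function(h)
    list(leaf_id = h$leaf_id, threshold = h$threshold,
         model = phmm_from_list(h$phmm)))
  names(hmms) <- vapply(hmms, `[[`, "", "leaf_id")
  slx <- x$second_layer
  SV <- do.call(rbind, lapply(slx$SV, unlist))
  second <- list(C = slx$C, gamma = slx$gamma, SV = SV,
                 coefs = unlist(slx$coefs), rho = slx$rho,
                 flip = isTRUE(slx$flip), platt = unlist(slx$platt),
                 prob_threshold = slx$prob_threshold)
  class(second) <- "second_layer"
  cfg_path <- file.path(dir, "run_config.json")
  config <- if (file.exists(cfg_path))
    jsonlite::read_json(cfg_path, simplifyVector = TRUE) else NULL
  model <- list(w = x$w, scheme = scheme, tree = x$tree, hmms = hmms,
                second_layer = second, config = config,
                metadata = x$metadata)
  model$metadata$leaf_sizes <- stats::setNames(
    vapply(hmms, function(h) h$model$n_train, integer(1)), names(hmms))
  class(model) <- "two_layer_model"
  model
}
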