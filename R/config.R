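## Run configuration: schema, defaults, validation, YAML (de)serialization.

.architectures <- c("vanillix", "varix", "stackix", "ontix", "xmodalix")

config_defaults <- function() {
  list(
    architecture = "varix",
    latent_dim = NULL,              # required
    beta_final = 1.0,
    anneal_steepness = NULL,        # default 15 / epochs, resolved at validation
    anneal_midpoint = 0.5,
    encoding_factor = 4,
    n_hidden = 2L,
    dropout = 0.1,
    learning_rate = 1e-4,
    weight_decay = 0,
    epochs = 100L,
    batch_size = 64L,
    pretrain_epochs = 0L,
    recon_loss = "mse",
    sim_loss = "kl",
    gamma = 0,
    delta_paired = 0,
    delta_class = 0,
    split = list(train = 0.6, valid = 0.2, test = 0.2),
    seed = 42L,
    filter = list(method = "none", k = NULL),
    scaler = list(method = "standard"),
    data = NULL,
    annotation = NULL,
    tasks = NULL,
    ontology = NULL,
    translate = NULL
  )
}

#' Build and validate a run configuration
#'
#' All hyperparameters of a pipeline run live in one flat configuration:
#' architecture choice, latent dimension, the KL/MMD weight `beta_final` with
#' its logistic annealing steepness and midpoint, the encoding factor that
#' shrinks successive hidden layers, optimizer settings, loss weights of the
#' cross-modal alignment terms (`gamma`, `delta_paired`, `delta_class`),
#' split ratios and filtering/scaling choices. Unknown keys are hard errors so
#' that misspelled options never silently fall back to defaults.
#'
#' @param ... configuration values (see `config_defaults()` internals for the
#'   full key set). `latent_dim` is required.
#' @return a validated object of class `run_config`.
#' @export
run_config <- function(...) {
  user <- list(...)
  if (length(user) == 1L && is.list(user[[1]]) && is.null(names(user))) {
    user <- user[[1]]
  }
  defaults <- config_defaults()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("config error: unknown key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, user, keep.null = TRUE)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("config validation error: ", msg)
  chk(is.character(cfg$architecture) && cfg$architecture %in% .architectures,
      paste0("architecture must be one of ", paste(.architectures, collapse = ", ")))
  chk(!is.null(cfg$latent_dim), "latent_dim is required")
  chk(is.numeric(cfg$latent_dim) && cfg$latent_dim >= 1 &&
        cfg$latent_dim == round(cfg$latent_dim), "latent_dim must be a positive integer")
  cfg$latent_dim <- as.integer(cfg$latent_dim)
  chk(cfg$beta_final >= 0, "beta_final must be nonnegative")
  chk(cfg$encoding_factor > 0, "encoding_factor must be positive")
  chk(cfg$n_hidden >= 1, "n_hidden must be a positive integer")
  cfg$n_hidden <- as.integer(cfg$n_hidden)
  chk(cfg$dropout >= 0 && cfg$dropout < 1, "dropout must be in [0, 1)")
  chk(cfg$learning_rate > 0, "learning_rate must be positive")
  chk(cfg$weight_decay >= 0, "weight_decay must be nonnegative")
  for (nm in c("epochs", "batch_size", "pretrain_epochs")) {
    chk(cfg[[nm]] >= 0 && cfg[[nm]] == round(cfg[[nm]]),
        paste(nm, "must be a nonnegative integer"))
    cfg[[nm]] <- as.integer(cfg[[nm]])
  }
  chk(cfg$batch_size >= 1, "batch_size must be at least 1")
  chk(cfg$recon_loss %in% c("mse", "bce"), "recon_loss must be 'mse' or 'bce'")
  chk(cfg$sim_loss %in% c("kl", "mmd"), "sim_loss must be 'kl' or 'mmd'")
  for (nm in c("gamma", "delta_paired", "delta_class")) {
    chk(cfg[[nm]] >= 0, paste(nm, "must be nonnegative"))
  }
  sp <- cfg$split
  if (is.numeric(sp) && length(sp) == 3L) {
    sp <- list(train = sp[[1]], valid = sp[[2]], test = sp[[3]])
  }
  chk(is.list(sp) && all(c("train", "valid", "test") %in% names(sp)),
      "split must give train/valid/test ratios")
  ratios <- unlist(sp[c("train", "valid", "test")])
  chk(all(ratios >= 0), "split ratios must be nonnegative")
  chk(abs(sum(ratios) - 1) < 1e-8, "split ratios must sum to 1")
  cfg$split <- as.list(ratios)
  chk(cfg$anneal_midpoint > 0 && cfg$anneal_midpoint < 1,
      "anneal_midpoint must be in (0, 1)")
  if (is.null(cfg$anneal_steepness)) {
    cfg$anneal_steepness <- 15 / max(1L, cfg$epochs)
  }
  chk(cfg$anneal_steepness > 0, "anneal_steepness must be positive")
  chk(is.numeric(cfg$seed), "seed must be numeric")
  cfg$seed <- as.integer(cfg$seed)
  chk(is.list(cfg$filter) && !is.null(cfg$filter$method), "filter needs a method")
  chk(cfg$filter$method %in% c("none", "variance", "mad", "correlation"),
      "filter method must be none/variance/mad/correlation")
  if (cfg$filter$method != "none") {
    chk(!is.null(cfg$filter$k) && cfg$filter$k >= 1, "filter needs k >= 1")
  }
  chk(is.list(cfg$scaler) && !is.null(cfg$scaler$method), "scaler needs a method")
  chk(cfg$scaler$method %in% c("standard", "minmax", "robust", "maxabs", "none"),
      "scaler method must be standard/minmax/robust/maxabs/none")
  if (cfg$architecture == "ontix" &&
      (is.null(cfg$ontology) || is.null(cfg$ontology$lvl1))) {
    stop("config validation error: architecture 'ontix' requires an ontology ",
         "(ontology: {lvl1: <edges.tsv>[, lvl2: <edges.tsv>]})")
  }
  if (cfg$recon_loss == "bce" && cfg$scaler$method %in% c("standard", "robust")) {
    stop("config validation error: recon_loss 'bce' requires inputs in [0,1]; ",
         "use scaler minmax (or none on already-bounded data)")
  }
  structure(cfg, class = "run_config")
}

#' Load and validate a YAML run configuration
#'
#' @param path YAML file; a flat mapping plus optional nested `filter`,
#'   `scaler`, `split`, `data`, `ontology`, `translate` sections.
#' @return a validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config error: YAML root must be a mapping")
  run_config(raw)
}

#' Serialize a run configuration to YAML
#' @param cfg a `run_config`.
#' @param path optional output file; if omitted, the YAML string is returned.
#' @export
save_config <- function(cfg, path = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  txt <- yaml::as.yaml(unclass(cfg), precision = 15L)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Stable hash of a configuration (key order independent)
#' @keywords internal
config_hash <- function(cfg) {
  x <- unclass(cfg)
  x <- x[order(names(x))]
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, null = "null",
                              digits = NA, force = TRUE), tf)
  unname(tools::md5sum(tf))
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> %s | L_dim=%d beta_final=%g epochs=%d lr=%g\n",
              x$architecture, x$latent_dim, x$beta_final, x$epochs,
              x$learning_rate))
  invisible(x)
}
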