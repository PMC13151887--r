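#' Default run configuration
#'
#' Reference-scale defaults: 12-layer, 256-dim denoiser conditioned at
#' layers \{3, 6, 9, 12\}; 1000 diffusion steps with a 100-step DDIM
#' sub-schedule and loss weights (0.1, 0.5); a 4-layer, 8-head conditioner
#' with 64-dim property encodings and a 5 percent target tolerance; the RL
#' hyperparameters of [rl_config()]; criteria thresholds QED >= 0.70,
#' SA <= 3.5, novelty >= 0.90; batch size 128 over 100 epochs.  The `train`
#' section additionally carries desk-scale knobs (rollout atom-count range,
#' PPO step sub-sampling, gradient-accumulation chunk).
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    seed = 42L,
    diffusion = list(T = 1000L, ddim_steps = 100L,
                     lambda_bond = 0.1, lambda_valence = 0.5),
    model = list(layers = 12L, hidden = 256L, t_dim = 64L, dist_scale = 2),
    conditioning = list(layers = c(3L, 6L, 9L, 12L), tolerance = 0.05,
                        encode_dim = 64L, model_dim = 256L,
                        transformer_layers = 4L, heads = 8L),
    rl = unclass(rl_config()),
    metrics = list(criteria = list(qed_min = 0.70, sa_max = 3.5,
                                   novelty_min = 0.90)),
    train = list(epochs = 100L, batch_size = 128L, iterations = 1L,
                 rollout_atoms = c(5L, 9L), ppo_sample_steps = 4L,
                 grad_accum = 4L)
  )
}

merge_config <- function(base, override, path = "") {
  for (nm in names(override)) {
    here <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(base)) stop("unknown config key: ", here)
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(override[[nm]])) stop("config key ", here,
                                         " must be a section")
      base[[nm]] <- merge_config(base[[nm]], override[[nm]], here)
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load and validate a YAML run configuration
#'
#' Unknown keys are rejected; missing keys fall back to [default_config()].
#'
#' @param path YAML file path (NULL for pure defaults).
#' @return Validated configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read configuration files")
    }
    user <- yaml::read_yaml(path)
    cfg <- merge_config(cfg, user)
  }
  cfg
}
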