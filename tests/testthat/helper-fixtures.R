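# Shared fixtures: tiny model configurations and phantom builders used across
# the suite. Everything is generated in code at test time.

tiny_gen_config <- function(in_ch = 1L, out_ch = 3L, size = 32L) {
  generator_config(in_ch, out_ch, image_size = size, base_width = 4L,
                   d_model = 12L, n_heads = 3L, n_rstb = 1L,
                   n_stl_per_rstb = 2L, window_size = 4L, mlp_ratio = 2)
}

tiny_models <- function(size = 32L, seed = 1L) {
  models_new(tiny_gen_config(size = size), disc_base_width = 4L, seed = seed)
}

# every second phantom carries inclusions (lipid/calcium alternating)
make_phantoms <- function(n, size = 64L, seed0 = 1000L, labeled = TRUE) {
  lapply(seq_len(n), function(i) {
    path <- i %% 2L == 0L
    kind <- if (!path) "none" else if (i %% 4L == 0L) "calcium" else "lipid"
    generate_phantom(phantom_spec(
      height = size, width = size, seed = seed0 + i,
      pathology_kind = kind,
      pathology_count = if (path) 1L + i %% 2L else 0L,
      labeled = labeled
    ))
  })
}

# alternating normal / pathological held-out set
heldout_phantoms <- function(n, size = 64L, seed0 = 90000L) {
  lapply(seq_len(n), function(i) {
    path <- i %% 2L == 0L
    generate_phantom(phantom_spec(
      height = size, width = size, seed = seed0 + i,
      pathology_kind = if (path) c("lipid", "calcium")[1 + i %% 2] else "none",
      pathology_count = if (path) 2L else 0L, labeled = TRUE
    ))
  })
}

quintile_medians <- function(x) {
  q <- max(1L, floor(length(x) / 5))
  c(first = stats::median(x[seq_len(q)]),
    last = stats::median(x[seq.int(length(x) - q + 1L, length(x))]))
}
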