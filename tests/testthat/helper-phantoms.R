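# Shared fixtures: all phantoms are generated in code at test time.
# Unit tests use a coarse grid (1.0 x 0.6 x 0.6 mm) for speed; acceptance
# tests use the default acquisition-like spacing.

coarse_spacing <- c(1.0, 0.6, 0.6)

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

small_phantom <- function(..., spacing = coarse_spacing) {
  generate_phantom(phantom_spec(...), spacing = spacing)
}

# default clean coarse phantom + its segmentation, shared across files
clean_case <- function() {
  cached("clean_case", {
    ph <- small_phantom()
    m <- segment_airway(ph$volume)
    lm <- detect_landmarks(ph$volume, m)
    list(ph = ph, mask = m, landmarks = lm)
  })
}

# an airway_mask wrapper around a plain logical array (single main label)
as_fake_mask <- function(mask, spacing) {
  lab <- array(0L, dim(mask)); lab[mask] <- 1L
  structure(list(mask = mask, labels = lab, connected = TRUE,
                 provenance = lab, voi = NULL, spacing = spacing,
                 stats = list()),
            class = "airway_mask")
}
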