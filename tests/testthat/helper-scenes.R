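# Shared fixtures, all built in code.

# Homogeneous slab between two full-face plate electrodes along x.
# n_gap tissue layers of `spacing` mm => electric gap n_gap * spacing.
plate_scene <- function(n_gap = 10, spacing = 1, ny = 20, nz = 20) {
  g <- build_grid(c((n_gap + 2) * spacing, ny * spacing, nz * spacing),
                  spacing)
  sc <- new_scene(g, fill = "liver")
  nx <- g$shape[1]
  sc$labels[1, , ] <- ireplan:::label_code("electrode_active", 1)
  sc$labels[nx, , ] <- ireplan:::label_code("electrode_active", 2)
  sc$electrodes <- list(
    electrode(c(spacing / 2, ny * spacing / 2, nz * spacing / 2),
              c(1, 0, 0), 1),
    electrode(c((nx - 0.5) * spacing, ny * spacing / 2, nz * spacing / 2),
              c(1, 0, 0), 2))
  sc
}

# Two parallel needles along z spanning the full z extent (quasi-2D slab,
# comparable with the infinite two-wire conductance formula).
two_needle_scene <- function(spacing, radius = 0.5, d = 15, L = 20,
                             lateral = 60) {
  g <- build_grid(c(lateral, lateral, L), spacing)
  sc <- new_scene(g, fill = "liver")
  for (k in 1:2)
    sc <- place_electrode(sc, electrode(
      c(lateral / 2 + c(-1, 1)[k] * d / 2, lateral / 2, L), c(0, 0, 1), k,
      radius = radius, exposure_length = L, insulated_length = 0))
  sc
}

# Constant-conductivity material table (no field dependence).
frozen_materials <- function(sigma = 0.2) {
  m <- default_material_table()
  for (nm in c("liver", "tumor", "vessel")) {
    m$tissues[[nm]]$sigma0 <- sigma
    m$tissues[[nm]]$sigma_f <- sigma
  }
  m
}

as_protocol_df <- function(df) ireplan:::as_protocol(df)

# Shared coarse (2 mm) synthetic run: computed once per test session.
.cache <- new.env(parent = emptyenv())
coarse_run <- function() {
  if (is.null(.cache$run)) {
    sc <- synthetic_case(spacing = 2)
    .cache$run <- run_protocol(sc, default_material_table())
  }
  .cache$run
}
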