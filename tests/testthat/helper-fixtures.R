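# Shared fixtures, cached per test session: icosphere meshes and spectral
# bases are deterministic, so repeated construction is pure waste.

.fixtures <- new.env(parent = emptyenv())

fix_mesh <- function(subdiv) {
  key <- paste0("mesh", subdiv)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generate_icosphere(subdiv)
  .fixtures[[key]]
}

fix_basis <- function(subdiv, M_T = NULL, method = "auto") {
  mesh <- fix_mesh(subdiv)
  if (is.null(M_T)) M_T <- nrow(mesh$vertices)
  key <- sprintf("basis%d_%d_%s", subdiv, M_T, method)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- compute_spectrum(mesh, M_T, method = method)
  .fixtures[[key]]
}

fix_scenario <- function() {
  if (is.null(.fixtures$scenario))
    .fixtures$scenario <- two_bundle_scenario(fix_mesh(3), fix_basis(3))
  .fixtures$scenario
}

# a small closed mesh with exact-integer coordinates (octahedron), for
# tie-breaking and hand-computable checks
octahedron_mesh <- function() {
  v <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
             c(0, 0, 1), c(0, 0, -1))
  f <- rbind(c(0, 2, 4), c(2, 1, 4), c(1, 3, 4), c(3, 0, 4),
             c(2, 0, 5), c(1, 2, 5), c(3, 1, 5), c(0, 3, 5))
  surf_mesh(v, f)
}

# independent face-area computation used by the conservation checks
face_areas_oracle <- function(mesh) {
  f <- mesh$faces + 1L
  apply(cbind(f), 1, function(r) {
    a <- mesh$vertices[r[2], ] - mesh$vertices[r[1], ]
    b <- mesh$vertices[r[3], ] - mesh$vertices[r[1], ]
    cr <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
            a[1] * b[2] - a[2] * b[1])
    0.5 * sqrt(sum(cr^2))
  })
}
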