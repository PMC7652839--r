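# Plate mesh construction: one bilinear plane-stress quad per pixel, with the
# thickness field as the out-of-plane element thickness.
#
# Under in-plane tension the stress in a membrane scales as
# force / (width x thickness), so thin (groove) elements concentrate stress
# exactly as a 3-D grooved plate does, at a fraction of the cost. Because a
# plane-stress element has no out-of-plane bending degrees of freedom, the
# model is automatically equivalent to a plate grooved symmetrically on both
# faces: there is no through-thickness stress asymmetry to correct for.

#' Material parameters for the plate
#'
#' Defaults correspond to an effectively rigid, nearly incompressible
#' brittle material: a large Young's modulus keeps the structure from
#' deforming appreciably before cracking, and a Poisson ratio near 0.5 keeps
#' it almost incompressible. Crack onset depends only on the ratio of the
#' applied load to `max_principal_stress`, and the load ramp is
#' auto-calibrated, so the absolute scale of these values is immaterial.
#'
#' @param youngs_modulus Young's modulus E (Pa). Default 210e9.
#' @param poisson_ratio Poisson ratio in (0, 0.5). Default 0.49.
#' @param max_principal_stress Fracture threshold (Pa): the crack extends
#'   when the maximum principal stress reaches this value. Default 220e6.
#' @param fracture_energy Energy per unit area (J/m^2). Accepted for
#'   completeness; crack extension here is instantaneous-brittle, so the
#'   value is not consumed. Default 42200.
#' @return A `material_params` list.
#' @export
material_params <- function(youngs_modulus = 210e9,
                            poisson_ratio = 0.49,
                            max_principal_stress = 220e6,
                            fracture_energy = 42200) {
  check_scalar(youngs_modulus, "youngs_modulus")
  check_scalar(max_principal_stress, "max_principal_stress")
  check_scalar(fracture_energy, "fracture_energy")
  if (!is.numeric(poisson_ratio) || poisson_ratio <= 0 || poisson_ratio >= 0.5)
    stop_param("`poisson_ratio` must lie strictly between 0 and 0.5")
  structure(list(youngs_modulus = youngs_modulus,
                 poisson_ratio = poisson_ratio,
                 max_principal_stress = max_principal_stress,
                 fracture_energy = fracture_energy),
            class = "material_params")
}

# Node id on the structured grid: node (i, j), i in 0..nr, j in 0..nc.
node_id <- function(i, j, nc) i * (nc + 1L) + j + 1L

#' Build a structured plate mesh from a thickness field
#'
#' Creates a conforming structured quad mesh with one element per pixel:
#' an `nr x nc` thickness field yields `(nr+1) x (nc+1)` nodes and
#' `nr * nc` elements. Node `(i, j)` (0-based) sits at the corner shared by
#' pixels `(i, j)` and `(i+1, j+1)` (1-based); element `(i, j)` carries the
#' thickness of pixel `(i, j)` times `pixel_size`. All four border node sets
#' are marked constrained (fully fixed), which removes rigid-body modes for
#' any crack orientation.
#'
#' @param thickness A [thickness_map()] result or plain matrix of heights.
#' @param pixel_size Side length of a pixel, default 1 (nondimensional).
#' @param material A [material_params()] object.
#' @return A `plate_mesh` list: `nodes` (n x 2 matrix of (row, col) node
#'   coordinates), `elem2node` (nelem x 4, counter-clockwise), `h` (element
#'   thickness vector), `nr`, `nc`, `constrained` (logical per node),
#'   `material`, `pixel_size`.
#' @export
build_mesh <- function(thickness, pixel_size = 1, material = material_params()) {
  if (!is.matrix(thickness)) stop_input("`thickness` must be a matrix")
  check_scalar(pixel_size, "pixel_size")
  stopifnot(inherits(material, "material_params"))
  nr <- nrow(thickness); nc <- ncol(thickness)
  ij <- expand.grid(i = 0:nr, j = 0:nc)      # column-major over i first
  nodes <- cbind(row = ij$i, col = ij$j)
  # reorder to row-major node ids: id = i*(nc+1) + j + 1
  ord <- order(node_id(ij$i, ij$j, nc))
  nodes <- nodes[ord, , drop = FALSE]
  eij <- expand.grid(i = 1:nr, j = 1:nc)     # element (i, j) = pixel (i, j)
  e2n <- cbind(node_id(eij$i - 1L, eij$j - 1L, nc),
               node_id(eij$i - 1L, eij$j,      nc),
               node_id(eij$i,      eij$j,      nc),
               node_id(eij$i,      eij$j - 1L, nc))
  constrained <- nodes[, 1] == 0 | nodes[, 1] == nr | nodes[, 2] == 0 | nodes[, 2] == nc
  structure(list(nodes = nodes,
                 elem2node = e2n,
                 elem_ij = as.matrix(eij),
                 h = as.numeric(thickness) * pixel_size,
                 nr = nr, nc = nc,
                 constrained = constrained,
                 material = material,
                 pixel_size = pixel_size,
                 split_info = NULL),
            class = "plate_mesh")
}

#' @export
print.plate_mesh <- function(x, ...) {
  cat(sprintf("<plate_mesh> %d x %d elements, %d nodes (%d split), thickness [%.2f, %.2f]\n",
              x$nr, x$nc, nrow(x$nodes),
              if (is.null(x$split_info)) 0L else nrow(x$split_info),
              min(x$h), max(x$h)))
  invisible(x)
}

#' Export mesh tables
#'
#' Returns the mesh as plain tibbles for inspection or rendering.
#'
#' @param mesh A `plate_mesh`.
#' @return List with `nodes` and `elements` tibbles.
#' @export
mesh_tables <- function(mesh) {
  stopifnot(inherits(mesh, "plate_mesh"))
  list(nodes = tibble::tibble(id = seq_len(nrow(mesh$nodes)),
                              row = mesh$nodes[, 1], col = mesh$nodes[, 2],
                              constrained = mesh$constrained),
       elements = tibble::tibble(id = seq_len(nrow(mesh$elem2node)),
                                 n1 = mesh$elem2node[, 1], n2 = mesh$elem2node[, 2],
                                 n3 = mesh$elem2node[, 3], n4 = mesh$elem2node[, 4],
                                 thickness = mesh$h))
}
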