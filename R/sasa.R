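# Van der Waals radii (Angstrom) by element, Bondi-style values.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
VDW_DEFAULT <- 1.70

# Theoretical maximum SASA per residue type (Angstrom^2), Tien et al.-style
# values, used to normalize absolute SASA into relative exposure.
MAX_SASA <- c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
              GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
              LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
              SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)

# Deterministic quasi-uniform points on the unit sphere (golden spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

atom_radii <- function(elety) {
  elem <- toupper(substr(trimws(elety), 1L, 1L))
  r <- VDW_RADII[elem]
  r[is.na(r)] <- VDW_DEFAULT
  unname(r)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA with a deterministic golden-spiral test-point sphere: for
#' each atom, test points are placed on its probe-expanded sphere and counted
#' accessible when inside no neighboring expanded sphere. Per-residue SASA is
#' the sum over the residue's atoms; relative SASA divides by a tabulated
#' per-residue-type maximum (for residue types outside the standard 20, by the
#' residue's isolated-sphere area, which keeps toy models self-consistent).
#'
#' @param model A `pep_structure`.
#' @param probe_radius Solvent probe radius in Angstrom (default 1.4, water).
#' @param n_points Test points per atom (default 960); output is deterministic
#'   given `n_points`.
#' @param exposure_threshold Relative-SASA cutoff classifying a residue as
#'   exposed (default 0.25).
#' @return Object of class `accessibility_result`: data.frame with `chain`,
#'   `resno`, `resid`, `sasa`, `rel_sasa` (capped at 1), `exposed`; the
#'   parameters are carried as attributes.
#' @export
compute_sasa <- function(model, probe_radius = 1.4, n_points = 960L,
                         exposure_threshold = 0.25) {
  a <- model$atoms
  if (nrow(a) == 0L) stop("model has no atoms")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  radii <- atom_radii(a$elety) + probe_radius
  pts <- sphere_points(n_points)
  n <- nrow(a)
  d2 <- as.matrix(stats::dist(xyz))^2
  area <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (radii[i] + radii)^2 & seq_len(n) != i)
    test <- sweep(pts * radii[i], 2L, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dx <- test[, 1] - xyz[j, 1]; dy <- test[, 2] - xyz[j, 2]
      dz <- test[, 3] - xyz[j, 3]
      acc <- acc & (dx * dx + dy * dy + dz * dz >= radii[j]^2)
      if (!any(acc)) break
    }
    area[i] <- 4 * pi * radii[i]^2 * mean(acc)
  }
  key <- paste(a$chain, a$resno)
  iso <- 4 * pi * radii^2
  res_sasa <- tapply(area, key, sum)
  res_iso <- tapply(iso, key, sum)
  rt <- residue_table(model)
  rkey <- paste(rt$chain, rt$resno)
  sasa <- as.numeric(res_sasa[rkey])
  max_ref <- MAX_SASA[rt$resid]
  max_ref[is.na(max_ref)] <- as.numeric(res_iso[rkey])[is.na(max_ref)]
  rel <- pmin(1, sasa / max_ref)
  out <- data.frame(chain = rt$chain, resno = rt$resno, resid = rt$resid,
                    sasa = sasa, rel_sasa = rel,
                    exposed = rel >= exposure_threshold,
                    stringsAsFactors = FALSE)
  structure(out, class = c("accessibility_result", "data.frame"),
            probe_radius = probe_radius, n_points = n_points,
            exposure_threshold = exposure_threshold)
}
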