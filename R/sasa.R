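#' Shrake-Rupley solvent-accessible surface area
#'
#' Classic sphere-point SASA: each atom's solvent-expanded sphere
#' (van der Waals radius + probe) is sampled with a deterministic golden-
#' spiral point set; points falling inside any neighbouring atom's expanded
#' sphere are occluded, and the exposed fraction scales the sphere area.
#' Per-residue SASA is the sum over the residue's atoms; relative SASA
#' normalises by the residue's maximum exposure in an extended Gly-X-Gly
#' tripeptide (theoretical values of Tien et al. 2013).
#'
#' @param ens an [ensemble] (heavy atoms; hydrogens included if present).
#' @param frame frame index.
#' @param probe_radius solvent probe radius in Angstrom (water: 1.4).
#' @param n_points sphere sample points per atom.
#' @param fallback_radius radius used for elements missing from the table
#'   (NA, the default, makes unknown elements an error).
#' @return data.frame with one row per residue: `chain`, `resno`,
#'   `resname`, `sasa` (A^2), `rel_sasa` (NA for residues without a
#'   normalisation value).
#' @export
shrake_rupley_sasa <- function(ens, frame = 1L, probe_radius = 1.4,
                               n_points = 960L, fallback_radius = NA) {
  co <- frame_coords(ens, frame)
  radii <- vdw_radius(ens$atoms$element, fallback_radius)
  sphere <- golden_spiral_points(n_points)
  n <- nrow(co)
  r_exp <- radii + probe_radius
  area <- numeric(n)
  # neighbour prefilter via cell-free distance check per atom
  maxr <- max(r_exp)
  for (a in seq_len(n)) {
    d2 <- rowSums(sweep(co, 2, co[a, ])^2)
    nb <- which(d2 < (r_exp[a] + maxr)^2 & seq_len(n) != a)
    nb <- nb[d2[nb] < (r_exp[a] + r_exp[nb])^2]
    pts <- sweep(sphere * r_exp[a], 2, co[a, ], "+")
    if (length(nb)) {
      occluded <- rep(FALSE, nrow(pts))
      for (b in nb) {
        if (all(occluded)) break
        free <- which(!occluded)
        dd <- rowSums(sweep(pts[free, , drop = FALSE], 2, co[b, ])^2)
        occluded[free[dd < r_exp[b]^2]] <- TRUE
      }
      frac <- 1 - mean(occluded)
    } else {
      frac <- 1
    }
    area[a] <- frac * 4 * pi * r_exp[a]^2
  }
  rt <- residue_table(ens)
  sasa <- vapply(seq_len(nrow(rt)), function(k) {
    sum(area[rt$first[k]:rt$last[k]])
  }, numeric(1))
  maxs <- max_sasa_table()[rt$resname]
  data.frame(chain = rt$chain, resno = rt$resno, resname = rt$resname,
             sasa = sasa, rel_sasa = sasa / unname(maxs),
             stringsAsFactors = FALSE)
}

# deterministic near-uniform points on the unit sphere (golden spiral)
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# van der Waals radii by element (A); united-atom-style defaults
vdw_radius <- function(element, fallback = NA) {
  tab <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
           F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90)
  r <- tab[toupper(element)]
  if (anyNA(r)) {
    if (is.na(fallback)) {
      stop("no van der Waals radius for element(s): ",
           paste(unique(element[is.na(r)]), collapse = ", "),
           "; supply fallback_radius")
    }
    r[is.na(r)] <- fallback
  }
  unname(r)
}

# maximum residue SASA in extended Gly-X-Gly (A^2), theoretical values
max_sasa_table <- function() {
  c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167, GLU = 223,
    GLN = 225, GLY = 104, HIS = 224, ILE = 197, LEU = 201, LYS = 236,
    MET = 224, PHE = 240, PRO = 159, SER = 155, THR = 172, TRP = 285,
    TYR = 263, VAL = 174)
}
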