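#' Species inventory of the synapse model
#'
#' Enumerates every molecular species tracked on the lattice together with its
#' layer (NK membrane, supported bilayer, or cytosol) and mobility class.
#' Complexes are named by composition: `C0` = NKG2D·ULBP3, `C1` = C0·SFK,
#' `C2` = pDAP10·ULBP3, `C3` = C2·Vav1, `C4` = C3·SFK,
#' `C5` = pDAP10·pVav1·ULBP3; `K0` = KIR2DL2·HLA-C, `K1` = K0·SFK,
#' `K2` = pITIM·HLA-C, `K3` = K2·SHP1, `K4f` = K3·pVav1 (free pVav1 arm),
#' `K4c` = K3·C5 (complex-bound pVav1 arm).
#'
#' Mobility classes: free monomers diffuse, ligand-bound NKG2D complexes are
#' cluster-mobile (they form and transport microclusters), and all KIR2DL2
#' complexes plus co-clustered SFK are immobile.
#'
#' @return A data.frame with columns `species`, `layer`
#'   (`"nk-membrane"`, `"bilayer"`, `"cytosol"`), and `mobility`
#'   (`"diffusive"`, `"cluster-mobile"`, `"immobile"`).
#' @export
species_inventory <- function() {
  data.frame(
    species = c("N", "L", "C0", "C1", "C2", "C3", "C4", "C5",
                "SFK", "SFKc", "Vav1", "pVav1", "SHP1",
                "K", "H", "K0", "K1", "K2", "K3", "K4f", "K4c"),
    layer = c("nk-membrane", "bilayer", rep("nk-membrane", 6),
              "nk-membrane", "nk-membrane", "cytosol", "cytosol", "cytosol",
              "nk-membrane", "bilayer", rep("nk-membrane", 6)),
    mobility = c("diffusive", "diffusive", rep("cluster-mobile", 6),
                 "diffusive", "immobile", "diffusive", "diffusive",
                 "diffusive",
                 "diffusive", "diffusive", rep("immobile", 6)),
    stringsAsFactors = FALSE
  )
}

#' @rdname species_inventory
#' @export
species_names <- function() species_inventory()$species

# Moiety incidence: how many copies of each conserved moiety a species carries.
# Used for conservation checks and for the NKG2D / pVav1 observable fields.
moiety_matrix <- function() {
  sp <- species_names()
  m <- matrix(0L, nrow = length(sp), ncol = 7,
              dimnames = list(sp, c("NKG2D", "ULBP3", "SFK", "Vav1",
                                    "SHP1", "KIR2DL2", "HLAC")))
  m[c("N", "C0", "C1", "C2", "C3", "C4", "C5", "K4c"), "NKG2D"] <- 1L
  m[c("L", "C0", "C1", "C2", "C3", "C4", "C5", "K4c"), "ULBP3"] <- 1L
  m[c("SFK", "SFKc", "C1", "C4", "K1"), "SFK"] <- 1L
  m[c("Vav1", "pVav1", "C3", "C4", "C5", "K4f", "K4c"), "Vav1"] <- 1L
  m[c("SHP1", "K3", "K4f", "K4c"), "SHP1"] <- 1L
  m[c("K", "K0", "K1", "K2", "K3", "K4f", "K4c"), "KIR2DL2"] <- 1L
  m[c("H", "K0", "K1", "K2", "K3", "K4f", "K4c"), "HLAC"] <- 1L
  m
}

# Species carrying a phosphorylated Vav1 moiety (drives the clustering
# potential and the centripetal saturation).
pvav1_species <- function() c("pVav1", "C5", "K4f", "K4c")

# Species carrying an NKG2D moiety (the imaged receptor field).
nkg2d_species <- function() c("N", "C0", "C1", "C2", "C3", "C4", "C5", "K4c")
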