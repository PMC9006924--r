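# Packaged datasets: the curated guest, affinity, noble-gas and solvent
# tables that parameterize the pre-formed cavity model. Values are stored at
# their published 2-decimal precision; derived quantities therefore compare
# with tolerances of ~0.01 kcal/mol.

# 21 rigid hydrocarbons: id, name, isodensity volume (A^3), effective
# hard-sphere diameter (A), static polarizability (A^3), solvation free
# energies (kcal/mol, 1 M gas -> 1 M solution) in water / benzene /
# perfluorohexane, cavitation energies (kcal/mol) in benzene /
# perfluorohexane, and gas->cavity transfer free energies (kcal/mol, molar
# gas reference state) for CB[6], CB[7] and CB[8]P2 (absolute).
.hydrocarbon_table <- function() {
  df <- utils::read.csv(text = '
id,name,volume,sigma_prime,alpha,solv_water,solv_benzene,solv_pfh,cav_benzene,cav_pfh,CB6,CB7,CB8.P2
1,Methane,33.7,3.70,2.50,1.39,-0.18,0.39,4.89,1.51,NA,-3.35,1.94
2,Ethane,53.6,4.32,4.27,1.61,-0.97,-0.18,6.58,1.93,-4.37,-3.21,2.02
3,Ethene,45.1,4.07,4.10,0.85,-1.11,-0.21,5.88,1.76,NA,-3.30,NA
4,Acetylene,36.6,3.80,3.44,-0.34,-1.27,-0.13,5.14,1.57,NA,-3.21,NA
5,Propane,73.3,4.79,6.08,1.77,-1.64,-0.67,8.11,2.31,-5.40,-3.38,0.21
6,Propene,64.8,4.60,5.99,0.85,-1.89,-0.75,7.46,2.15,NA,-3.34,NA
7,cis-Butene,84.4,5.02,7.85,0.79,-2.73,-1.36,8.94,2.51,-6.27,-5.41,-2.80
8,trans-Butene,84.5,5.02,7.93,1.06,-2.63,-1.32,8.95,2.51,NA,-4.60,-0.82
9,Isobutane,92.7,5.18,7.88,1.82,-2.24,-1.10,9.55,2.66,-6.27,-5.58,-0.21
10,Isobutene,84.3,5.02,7.84,0.83,-2.54,-1.20,8.93,2.51,-5.89,-5.49,-1.64
11,Neopentane,111.8,5.51,9.67,1.81,-2.76,-1.48,10.91,2.98,NA,-6.38,-3.39
12,Cyclopentane,99.7,5.31,8.79,1.07,-3.30,-2.05,10.06,2.78,-7.26,-6.15,-1.42
13,Cyclopentene,91.5,5.16,8.66,0.36,-3.53,-2.13,9.46,2.64,-6.66,NA,-2.93
14,Cyclohexane,118.5,5.62,10.54,1.02,-3.96,-2.57,11.38,3.09,NA,-7.41,-1.46
15,Cyclohexene,110.2,5.49,10.41,0.16,-4.28,-2.68,10.80,2.95,NA,NA,NA
16,"1,3-Cyclohexadiene",101.9,5.34,10.43,-0.52,-4.50,-2.73,10.21,2.81,NA,NA,-4.24
17,"1,4-Cyclohexadiene",102.0,5.35,10.24,-0.67,-4.69,-2.89,10.22,2.82,NA,NA,NA
18,Benzene,93.3,5.19,10.13,-0.94,-4.73,-2.89,9.59,2.67,NA,-6.71,-3.99
19,Cycloheptene,129.1,5.78,12.24,-0.04,-5.05,-3.26,12.11,3.26,NA,NA,NA
20,Norbornene,117.8,5.61,11.30,-0.04,-4.66,-2.96,11.33,3.08,NA,-7.89,NA
21,Cyclooctatetraene,123.9,5.70,13.97,-1.90,-6.39,-4.00,11.75,3.18,NA,NA,NA
', stringsAsFactors = FALSE, colClasses = c(id = "character"))
  df
}

# Competitive titration results for the CB[8]/auxiliary-probe cavities:
# relative binding constants of 9 rigid hydrocarbons (K normalized to
# cycloheptene = 1000 for the P3 probe, and to benzene = 1 for both probes)
# and the derived transfer free energies from aqueous solution (ddG_aq) and
# from the gas phase (ddG_gas), all in kcal/mol relative to benzene.
.affinity_table <- function() {
  df <- utils::read.csv(text = '
id,name,K_cycloheptene_P3,K_cycloheptene_P3_se,K_benzene_P1,K_benzene_P3,K_benzene_P3_se,ddG_aq_P1,ddG_aq_P3,ddG_aq_P3_se,ddG_gas_P1,ddG_gas_P3
12,Cyclopentane,22.1,0.6,14,9.9,0.3,-1.56,-1.36,0.02,0.46,0.66
13,Cyclopentene,4.7,0.2,5.6,2.1,0.1,-1.02,-0.44,0.03,0.28,0.86
14,Cyclohexane,244,4,160,110,2,-3.01,-2.78,0.01,-1.04,-0.82
15,Cyclohexene,38.0,0.6,14,17.0,0.3,-1.56,-1.68,0.01,-0.46,-0.58
16,"1,3-Cyclohexadiene",6.3,0.5,2.2,2.8,0.2,-0.47,-0.62,0.05,-0.05,-0.20
17,"1,4-Cyclohexadiene",13,1,4.2,5.8,0.4,-0.85,-1.04,0.04,-0.57,-0.76
18,Benzene,2.2,0.1,1.0,1.00,0.05,0.00,0.00,0.03,0.00,0.00
19,Cycloheptene,1000,NA,140,448,NA,-2.93,-3.62,NA,-2.02,-2.71
21,Cyclooctatetraene,747,71,5.6,334,32,-1.02,-3.44,0.06,-1.97,-4.40
', stringsAsFactors = FALSE, colClasses = c(id = "character"))
  df
}

# Noble gases He-Xe plus methane (1) and ethane (2): solvation, cavitation,
# the 68:32 perfluorohexane/benzene mixture dispersion term (with the
# quantum-chemical reference value in disp_mix_ref), and gas->CB[5] transfer
# free energies (transfer_csmd: literature value from an independent
# solvation model).
.noblegas_table <- function() {
  df <- utils::read.csv(text = '
id,name,solv_water,solv_benzene,solv_pfh,cav_benzene,cav_pfh,disp_mix_6832,disp_mix_ref,CB5,CB5_csmd
He,Helium,2.90,2.54,2.51,2.15,0.77,1.31,1.8,0.30,0.1
Ne,Neon,2.92,2.33,2.33,2.64,0.91,0.87,0.5,0.42,0.1
Ar,Argon,2.24,0.93,1.20,4.09,1.30,-1.07,-1.4,-1.26,-1.5
Kr,Krypton,1.91,0.53,0.89,4.67,1.45,-1.70,-3.2,-2.69,-3.0
Xe,Xenon,1.77,-0.19,0.31,5.66,1.70,-2.82,-4.9,-3.63,-4.1
1,Methane,1.39,-0.18,0.39,4.89,1.51,-2.38,-2.3,-3.01,-2.4
2,Ethane,1.61,-0.97,-0.18,6.58,1.93,NA,NA,-0.29,-0.1
', stringsAsFactors = FALSE, colClasses = c(id = "character"))
  df
}

#' Load a packaged dataset
#'
#' Returns one of the curated tables shipped with the package:
#' \describe{
#'   \item{`table1`}{Competitive-titration affinities and transfer energies
#'     for the CB\[8\] probe cavities (9 rigid hydrocarbons).}
#'   \item{`table2`}{Physicochemical and thermodynamic properties of the 21
#'     hydrocarbon guests, plus absolute gas->cavity transfer energies for
#'     CB\[6\], CB\[7\] and CB\[8\]P2.}
#'   \item{`table3`}{Noble gases (He-Xe), methane and ethane: solvation,
#'     cavitation, mixture dispersion terms and gas->CB\[5\] transfer
#'     energies.}
#'   \item{`solvents`}{The calibrated mimic-solvent registry (see
#'     [cb_solvents()]).}
#' }
#' Each data frame carries a `"provenance"` attribute mapping column names
#' to their published source.
#'
#' @param table One of `"table1"`, `"table2"`, `"table3"`, `"solvents"`.
#' @return A data frame (or, for `"solvents"`, a named list of
#'   [solvent_model()] objects).
#' @examples
#' head(cb_table("table2"))
#' @export
cb_table <- function(table = c("table1", "table2", "table3", "solvents")) {
  if (!is.character(table) || length(table) != 1L ||
      !table %in% c("table1", "table2", "table3", "solvents")) {
    stop("cb_table: unknown table id; use table1, table2, table3 or solvents")
  }
  out <- switch(table,
    table1 = {
      df <- .affinity_table()
      attr(df, "provenance") <- c(
        K_cycloheptene_P3 = "affinity table, K relative to cycloheptene (P3)",
        K_benzene_P1 = "affinity table, K relative to benzene (P1)",
        K_benzene_P3 = "affinity table, K relative to benzene (P3)",
        ddG_aq_P1 = "affinity table, transfer from water (P1)",
        ddG_aq_P3 = "affinity table, transfer from water (P3)",
        ddG_gas_P1 = "affinity table, transfer from gas (P1)",
        ddG_gas_P3 = "affinity table, transfer from gas (P3)")
      df
    },
    table2 = {
      df <- .hydrocarbon_table()
      attr(df, "provenance") <- c(
        volume = "guest table, col V (PM6 isodensity)",
        sigma_prime = "guest table, col sigma'",
        alpha = "guest table, col alpha",
        solv_water = "guest table, dG_solv H2O (COSMO-RS)",
        solv_benzene = "guest table, dG_solv C6H6 (COSMO-RS)",
        solv_pfh = "guest table, dG_solv C6F14 (COSMO-RS)",
        cav_benzene = "guest table, dG_cav C6H6 (hard-sphere EOS)",
        cav_pfh = "guest table, dG_cav C6F14 (hard-sphere EOS)",
        CB6 = "guest table, dG gas->CB[6]",
        CB7 = "guest table, dG gas->CB[7]",
        CB8.P2 = "guest table, dG gas->CB[8]P2")
      df
    },
    table3 = {
      df <- .noblegas_table()
      attr(df, "provenance") <- c(
        solv_water = "noble-gas table, dG_solv H2O",
        solv_benzene = "noble-gas table, dG_solv C6H6",
        solv_pfh = "noble-gas table, dG_solv C6F14",
        cav_benzene = "noble-gas table, dG_cav C6H6",
        cav_pfh = "noble-gas table, dG_cav C6F14",
        disp_mix_6832 = "noble-gas table, dG_disp 68:32 C6F14/C6H6",
        CB5 = "noble-gas table, dG gas->CB[5]")
      df
    },
    solvents = cb_solvents()
  )
  out
}

#' Full packaged guest table
#'
#' The 21 hydrocarbons plus the 5 noble gases in a single guest table with a
#' common schema (`id`, `name`, `volume`, `sigma_prime`, `alpha`,
#' `solv_water`, `solv_benzene`, `solv_pfh`, `cav_benzene`, `cav_pfh`).
#' Noble gases lack computed volumes and polarizabilities (`NA`).
#'
#' @return A data frame with 26 rows.
#' @examples
#' g <- cb_guests()
#' subset(g, id %in% c("1", "Xe"))
#' @export
cb_guests <- function() {
  hc <- .hydrocarbon_table()
  ng <- .noblegas_table()
  ng <- ng[!ng$id %in% hc$id, ]
  cols <- c("id", "name", "volume", "sigma_prime", "alpha", "solv_water",
            "solv_benzene", "solv_pfh", "cav_benzene", "cav_pfh")
  hc <- hc[cols]
  for (cn in setdiff(cols, names(ng))) ng[[cn]] <- NA_real_
  out <- rbind(hc, ng[cols])
  rownames(out) <- NULL
  out
}
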