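## Regenerates the bundled synthetic bulk dielectric tables from the
## package's analytic models. Run from the repository root:
##   Rscript tools/make-fixtures.R
pkgload::load_all(".", quiet = TRUE)

write_table <- function(metal, path) {
  lam <- seq(300, 800)
  eps <- synthetic_bulk_dielectric(metal, lam)
  con <- file(path, "w")
  writeLines(c(
    sprintf("# Synthetic bulk dielectric function of %s, model-generated", metal),
    "# (Drude free-electron term plus, for gold, a logistic interband",
    "# increment; see ?synthetic_bulk_dielectric). Effective parameters are",
    "# anchored to the bundled reference worked-example dielectric at 539 nm",
    "# under the size-multiplier correction. Stand-in for measured bulk",
    "# optical constants, not a measurement."
  ), con)
  utils::write.csv(
    data.frame(wavelength_nm = lam,
               eps_real = round(Re(eps), 6),
               eps_imag = round(Im(eps), 6)),
    con, row.names = FALSE)
  close(con)
  cat("wrote", path, "\n")
}
dir.create("inst/extdata", showWarnings = FALSE, recursive = TRUE)
write_table("gold", "inst/extdata/gold_dielectric_synthetic.csv")
write_table("silver", "inst/extdata/silver_dielectric_synthetic.csv")
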