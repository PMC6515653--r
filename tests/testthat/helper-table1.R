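# Published per-species census of the three sugar-transporter families
# (four taxa: the holoparasite, the two hemiparasites, and the
# non-parasitic relative), used to exercise the census arithmetic.
published_census <- local({
  species <- c("PaAe", "StHe", "TvVe", "MiGu")
  counts <- list(
    MST = list(
      ERD6     = c(5, 8, 6, 6),
      pGLT_SGB = c(2, 2, 3, 4),
      INT      = c(3, 7, 3, 6),
      TMT      = c(6, 2, 3, 4),
      PMT      = c(7, 20, 23, 7),
      VGT      = c(2, 2, 3, 2),
      STP      = c(9, 25, 22, 17)),
    SUT = list(
      SUT1 = c(2, 5, 3, 2),
      SUT2 = c(1, 1, 1, 1),
      SUT4 = c(1, 3, 1, 1)),
    SWEET = list(
      `Clade I`   = c(8, 8, 5, 10),
      `Clade II`  = c(0, 5, 3, 3),
      `Clade III` = c(6, 10, 5, 14),
      `Clade IV`  = c(0, 2, 0, 2)))
  percents <- list(
    MST = list(
      ERD6     = c("14.71%", "12.12%", "9.52%", "13.04%"),
      pGLT_SGB = c("5.88%", "3.03%", "4.76%", "8.70%"),
      INT      = c("8.82%", "10.61%", "4.76%", "13.04%"),
      TMT      = c("17.65%", "3.03%", "4.76%", "8.70%"),
      PMT      = c("20.59%", "30.30%", "36.51%", "15.22%"),
      VGT      = c("5.88%", "3.03%", "4.76%", "4.35%"),
      STP      = c("26.47%", "37.88%", "34.92%", "36.96%")),
    SUT = list(
      SUT1 = c("50.00%", "55.56%", "60.00%", "50.00%"),
      SUT2 = c("25.00%", "11.11%", "20.00%", "25.00%"),
      SUT4 = c("25.00%", "33.33%", "20.00%", "25.00%")),
    SWEET = list(
      `Clade I`   = c("57.14%", "32.00%", "38.46%", "34.48%"),
      `Clade II`  = c("0.00%", "20.00%", "23.08%", "10.34%"),
      `Clade III` = c("42.86%", "40.00%", "38.46%", "48.28%"),
      `Clade IV`  = c("0.00%", "8.00%", "0.00%", "6.90%")))
  totals <- list(MST = c(34, 66, 63, 46), SUT = c(4, 9, 5, 4),
                 SWEET = c(14, 25, 13, 29))
  list(species = species, counts = counts, percents = percents,
       totals = totals)
})

published_assignments <- function() {
  pc <- published_census
  rows <- NULL
  for (fam in names(pc$counts)) {
    for (clade in names(pc$counts[[fam]])) {
      for (s in seq_along(pc$species)) {
        n <- pc$counts[[fam]][[clade]][s]
        if (n == 0) next
        sp <- pc$species[s]
        ids <- sprintf("%s_%s_%s_%d", sp, fam, gsub(" ", "", clade),
                       seq_len(n))
        rows <- rbind(rows, data.frame(
          id = ids, species = sp, family = fam, clade = clade,
          stringsAsFactors = FALSE))
      }
    }
  }
  rows
}
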