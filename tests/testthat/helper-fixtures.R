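# shared fixture builders: everything generated in code, nothing on disk

# minimal two-well readings CSV; returns the path
writeToyReadingsCSV <- function(extraLines = character()) {
  tf <- tempfile(fileext = ".csv")
  writeLines(c("plate_id,well,sample_id,role,read_stage,rfu",
               "P1,A1,S1,test,pre_wash,2500",
               "P1,A2,S1,test,pre_wash,2400",
               extraLines), tf)
  tf
}

# manifest CSV with nMZ + nSIB pairs and full covariate columns
writeToyManifestCSV <- function(nMZ = 3, nSIB = 3, mangle = identity) {
  n <- nMZ + nSIB
  df <- data.frame(
    pair_id = sprintf("PR%02d", seq_len(n)),
    zygosity = rep(c("mz", "Sib"), c(nMZ, nSIB)),   # case-insensitive parse
    sample_id_a = sprintf("A%02d", seq_len(n)),
    sample_id_b = sprintf("B%02d", seq_len(n)),
    age = 30 + seq_len(n), sex = rep(c("F", "M"), length.out = n))
  df <- mangle(df)
  tf <- tempfile(fileext = ".csv")
  write.csv(df, tf, row.names = FALSE, quote = FALSE)
  tf
}

# exact 4PL evaluation, independent of the package's evalFourPL
fourPLRef <- function(x, a, d, cc, b) d + (a - d) / (1 + (x / cc)^b)

# a small noiseless FourPLCurve for inversion tests
toyCurve <- function(a = 100, d = 5000, cc = 2e4, b = 1.5) {
  x <- c(200, 500, 2000, 8000, 2e4, 5e4, 1e5)
  fitFourPL(x, fourPLRef(x, a, d, cc, b))
}

# correlated pair phenotypes (bivariate normal, exchangeable members)
rPairs <- function(n, rho, mean = 0, sdev = 1) {
  shared <- rnorm(n)
  a <- sqrt(rho) * shared + sqrt(1 - rho) * rnorm(n)
  b <- sqrt(rho) * shared + sqrt(1 - rho) * rnorm(n)
  data.frame(y_a = mean + sdev * a, y_b = mean + sdev * b)
}
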