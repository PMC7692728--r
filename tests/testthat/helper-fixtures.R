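# shared fixture: load the packaged inventory once per test file
.inv_cache <- new.env(parent = emptyenv())

phy_inv <- function() {
  if (is.null(.inv_cache$inv)) .inv_cache$inv <- phytohabitans_inventory()
  .inv_cache$inv
}

phy_line <- function(cluster_id, strain = NULL)
  assemble_line(get_cluster(phy_inv(), cluster_id, strain))

# brute-force longest-common-subsequence oracle (exponential-free DP-free
# recursion with memo kept tiny by the short inputs used in tests)
lcs_brute <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) return(0L)
  if (a[1] == b[1]) return(1L + lcs_brute(a[-1], b[-1]))
  max(lcs_brute(a[-1], b), lcs_brute(a, b[-1]))
}

# random ASCII architecture for round-trip property tests
random_architecture <- function() {
  kinds <- c("KS", "KS1", "AT_m", "AT_p", "AT_e", "AT", "ACP", "KR", "DH",
             "ER", "MT", "A", "A_ser", "A_val?", "T", "LCL", "DCL", "C_Du",
             "C_M", "C_S", "C_Cy", "C", "E", "TE", "TD", "CoL", "FkbH")
  n <- sample(1:12, 1)
  words <- sample(kinds, n, replace = TRUE)
  seps <- if (n > 1) sample(c("/", "-"), n - 1, replace = TRUE,
                            prob = c(0.8, 0.2)) else character()
  paste0(words[1], paste0(seps, words[-1], collapse = ""))
}
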