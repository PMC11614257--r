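# Shared fixtures, built in code.

# Minimal valid facility table: n rows, every item set to `fill` (0/1) or
# a function(n) returning a 0/1 vector per item column.
make_facility_table <- function(n = 2, fill = 1L,
                                region = "Oromia",
                                notified = 1L, reviewed = 1L) {
  df <- data.frame(
    facility_id = sprintf("F%03d", seq_len(n)),
    region = rep_len(region, n),
    facility_level = "primary",
    location = "rural",
    region_type = "agrarian",
    agro_zone = "midland",
    years_implementing = "ge2",
    notified_last_year = rep_len(notified, n),
    reviewed_last_year = rep_len(reviewed, n),
    stringsAsFactors = FALSE
  )
  for (col in item_columns()) {
    df[[col]] <- if (is.function(fill)) fill(n) else rep_len(fill, n)
  }
  df
}

# Published per-region indicator grid used as an anchor. The five cells in
# `loose_cells` disagree with exact recomputation from the printed counts
# by more than one-decimal rounding (source-side rounding); they are
# checked at a wider band.
printed_indicator_grid <- function() {
  read.csv(text = "region,Rn,CRn,CRr,Rr,CRDp,mdsrpi
Addis Ababa,82.1,15.0,12.1,80.6,17.9,34.2
Afar,46.3,6.8,6.1,89.7,52.6,31.7
Amhara,85.3,13.8,11.8,85.9,66.9,40.1
Benishangul-Gumuz,75.0,13.8,9.1,66.1,52.6,32.8
Dire Dawa,68.4,32.6,44.5,136.4,17.6,59.0
Gambella,52.9,11.3,8.4,74.4,59.4,32.0
Harari,79.6,64.7,45.7,70.7,9.2,56.1
Oromia,83.1,10.2,5.6,55.0,55.1,29.5
SNNPR,64.7,3.5,4.4,126.9,30.8,37.3
Somali,61.7,3.2,0.7,21.3,27.6,14.4
Tigray,44.3,9.8,20.8,213.6,78.4,64.2",
           stringsAsFactors = FALSE, check.names = FALSE)
}

loose_cells <- data.frame(
  region = c("Benishangul-Gumuz", "Gambella", "Harari", "Somali", "Harari"),
  indicator = c("Rn", "Rn", "Rn", "Rn", "CRr"),
  stringsAsFactors = FALSE
)

# Brute-force oracles, independent of the package implementation.
brute_mk_S <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) s <- s + sign(x[j] - x[i])
  }
  s
}

brute_sen_slope <- function(x, yr) {
  n <- length(x)
  sl <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) sl <- c(sl, (x[j] - x[i]) / (yr[j] - yr[i]))
  }
  median(sl)
}
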