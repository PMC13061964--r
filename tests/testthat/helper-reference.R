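# Published per-element risk results for the six-mushroom study table,
# kept as printed strings so tests can derive each value's printing
# precision (half-ULP). The child Laccaria laccata carcinogenic EDI cell
# is omitted: its printed form is a typographical artifact, and the
# adjacent CR cell validates the underlying value instead.
published_element_risk <- function() {
  txt <- "group,species,element,edi_noncarc,thq,edi_carc,cr
adult,Morchella importuna,Cd,1.539e-4,0.154,0.548e-4,3.455e-4
adult,Morchella importuna,Pb,2.883e-4,0.082,1.027e-4,8.728e-7
adult,Morchella importuna,As,2.800e-4,0.933,0.997e-4,1.496e-4
adult,Morchella importuna,Hg,0.021e-4,0.007,0.007e-4,4.547e-6
adult,Tricholoma scalpturatum,Cd,0.875e-4,0.087,0.312e-4,1.963e-4
adult,Tricholoma scalpturatum,Pb,0.969e-4,0.028,0.345e-4,2.936e-7
adult,Tricholoma scalpturatum,As,0.885e-4,0.295,0.315e-4,4.731e-5
adult,Tricholoma scalpturatum,Hg,0.0316e-4,0.011,0.011e-4,6.957e-6
adult,Infundibulicybe geotropa,Cd,3.301e-4,0.330,1.176e-4,7.408e-4
adult,Infundibulicybe geotropa,Pb,1.448e-4,0.041,0.516e-4,4.384e-7
adult,Infundibulicybe geotropa,As,1.736e-4,0.578,0.618e-4,9.273e-5
adult,Infundibulicybe geotropa,Hg,0.489e-4,0.163,0.174e-4,1.078e-4
adult,Tricholoma populinum,Cd,2.267e-4,0.227,0.807e-4,5.086e-4
adult,Tricholoma populinum,Pb,1.383e-4,0.039,0.493e-4,4.188e-7
adult,Tricholoma populinum,As,2.660e-4,0.887,0.948e-4,1.421e-4
adult,Tricholoma populinum,Hg,0.0213e-4,0.007,0.007e-4,4.682e-6
adult,Pholiota carbonaria,Cd,2.798e-4,0.279,0.997e-4,6.279e-4
adult,Pholiota carbonaria,Pb,2.062e-4,0.059,0.734e-4,6.243e-7
adult,Pholiota carbonaria,As,1.841e-4,0.614,0.656e-4,9.836e-5
adult,Pholiota carbonaria,Hg,0.084e-4,0.028,0.029e-4,1.852e-5
adult,Laccaria laccata,Cd,9.484e-4,0.948,3.378e-4,2.128e-3
adult,Laccaria laccata,Pb,2.057e-4,0.059,0.733e-4,6.229e-7
adult,Laccaria laccata,As,1.886e-4,0.629,0.672e-4,1.008e-4
child,Morchella importuna,Cd,4.210e-4,0.421,0.346e-4,2.180e-4
child,Morchella importuna,Pb,7.883e-4,0.225,0.648e-4,5.508e-7
child,Morchella importuna,As,7.657e-4,2.552,0.629e-4,9.440e-5
child,Morchella importuna,Hg,0.0565e-4,0.019,0.005e-4,2.869e-6
child,Tricholoma scalpturatum,Cd,2.392e-4,0.239,0.197e-4,1.239e-4
child,Tricholoma scalpturatum,Pb,2.652e-4,0.076,0.218e-4,1.853e-7
child,Tricholoma scalpturatum,As,2.421e-4,0.807,0.199e-4,2.985e-5
child,Tricholoma scalpturatum,Hg,0.086e-4,0.029,0.007e-4,4.390e-6
child,Infundibulicybe geotropa,Cd,9.028e-4,0.902,0.742e-4,4.675e-4
child,Infundibulicybe geotropa,Pb,3.960e-4,0.113,0.325e-4,2.767e-7
child,Infundibulicybe geotropa,As,4.746e-4,1.582,0.390e-4,5.852e-5
child,Infundibulicybe geotropa,Hg,1.339e-4,0.446,0.110e-4,6.800e-5
child,Tricholoma populinum,Cd,6.198e-4,0.619,0.509e-4,3.209e-4
child,Tricholoma populinum,Pb,3.783e-4,0.108,0.311e-4,2.643e-7
child,Tricholoma populinum,As,7.275e-4,2.424,0.598e-4,8.969e-5
child,Tricholoma populinum,Hg,0.058e-4,0.019,0.005e-4,2.954e-6
child,Pholiota carbonaria,Cd,7.652e-4,0.765,0.629e-4,3.962e-4
child,Pholiota carbonaria,Pb,5.638e-4,0.161,0.463e-4,3.939e-7
child,Pholiota carbonaria,As,5.034e-4,1.678,0.414e-4,6.207e-5
child,Pholiota carbonaria,Hg,0.230e-4,0.076,0.019e-4,1.168e-5
child,Laccaria laccata,Cd,25.933e-4,2.593,,1.343e-3
child,Laccaria laccata,Pb,5.626e-4,0.160,0.462e-4,3.931e-7
child,Laccaria laccata,As,5.157e-4,1.719,0.424e-4,6.358e-5"
  read.csv(text = txt, stringsAsFactors = FALSE, colClasses = "character")
}

# Published species-level hazard index and total carcinogenic risk.
published_species_risk <- function() {
  txt <- "group,species,hi,tcr
adult,Morchella importuna,1.177,5.005e-4
adult,Tricholoma scalpturatum,0.421,2.509e-4
adult,Infundibulicybe geotropa,1.113,9.418e-4
adult,Tricholoma populinum,1.160,6.558e-4
adult,Pholiota carbonaria,0.981,7.454e-4
adult,Laccaria laccata,1.636,2.229e-3
child,Morchella importuna,3.217,3.158e-4
child,Tricholoma scalpturatum,1.150,1.583e-4
child,Infundibulicybe geotropa,3.044,5.943e-4
child,Tricholoma populinum,3.172,4.138e-4
child,Pholiota carbonaria,2.681,4.703e-4
child,Laccaria laccata,4.473,1.407e-3"
  read.csv(text = txt, stringsAsFactors = FALSE, colClasses = "character")
}

# Half of one unit in the last printed decimal place, e.g. "0.548e-4" has
# 3 mantissa decimals so its half-ULP is 0.0005e-4.
half_ulp <- function(printed) {
  vapply(printed, function(s) {
    parts <- strsplit(s, "e", fixed = TRUE)[[1]]
    mant <- parts[1]
    expo <- if (length(parts) == 2) as.numeric(parts[2]) else 0
    dec <- if (grepl(".", mant, fixed = TRUE)) {
      nchar(strsplit(mant, ".", fixed = TRUE)[[1]][2])
    } else {
      0
    }
    0.5 * 10^(-dec) * 10^expo
  }, numeric(1), USE.NAMES = FALSE)
}

# Comparison tolerance for one printed cell: 0.5% computation slack plus
# the printed value's own half-ULP plus the slack induced by the source
# concentration table printing means truncated to 3 decimals (one input
# ULP of 0.001 mg/kg propagated through the linear model). `input_slack`
# is that last, already-propagated absolute term.
printed_tolerance <- function(printed, input_slack = 0) {
  0.005 * abs(as.numeric(printed)) + half_ulp(printed) + input_slack
}

# concentration-table means indexed as mean_lookup[["species|element"]]
mean_lookup <- function(tab) {
  setNames(tab$mean_conc, paste(tab$species, tab$element, sep = "|"))
}
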