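Total mass attenuation coefficients (coherent scattering included), cm^2/g,
versus photon energy in keV, over the diagnostically relevant 30-150 keV
range. Values transcribed from the NIST XCOM photon cross section database.
K-edge discontinuities (W 69.525 keV; Pb 88.005 keV; Bi 90.526 keV) are
represented by paired nodes offset by 1 eV so that each table remains
strictly increasing in energy and log-log interpolation stays well defined.
Densities in manifest.tsv are standard elemental values; gelatine is
modelled by the water entry at density 1.0 g/cm^3.
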