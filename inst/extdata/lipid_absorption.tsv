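# Absorption coefficient of pure lipid (purified vegetable oil surrogate).
# Units: wavelength_nm [nm]; mua_lipid [1/mm], natural (base-e) absorption
# coefficient at unit volume fraction; scaled by volume fraction when mixed.
# Provenance: approximate reconstruction of published purified-oil lipid
# absorption spectra (van Veen et al. style), anchored at the 930 nm band
# and the weak 760 nm overtone; NOT a verbatim copy of any single
# published table.
wavelength_nm	mua_lipid
650	0.00005
670	0.00006
700	0.00007
730	0.00015
745	0.00030
760	0.00055
780	0.00030
800	0.00022
820	0.00030
840	0.00050
860	0.00080
880	0.00200
890	0.00320
900	0.00500
915	0.00780
925	0.01100
930	0.01220
935	0.01120
940	0.00900
950	0.00550
960	0.00330
970	0.00280
980	0.00280
990	0.00300
1000	0.00330
1010	0.00370
1020	0.00420
1030	0.00480
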