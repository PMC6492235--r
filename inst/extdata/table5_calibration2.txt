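# Cross-calibrated fossil-style constraints for the synthetic 74-taxon
# reaction-center fixture (ages in Ga). Soft bounds: 2.5% tail mass per
# two-sided boundary, 5% for a single minimum. Profile 2: crown
# Cyanobacteria minimum at 2.70 Ga.

name: arabidopsis_populus_D1
tips: euk_D1_arabidopsis, euk_D1_populus
min: 0.082
max: 0.127

name: angiosperms_D1
tips: euk_D1_amborella, euk_D1_arabidopsis, euk_D1_populus
min: 0.124
max: 0.248

name: gymnosperms_D1
tips: euk_D1_cycas, euk_D1_amborella, euk_D1_arabidopsis, euk_D1_populus
min: 0.306
max: 0.366

name: land_plants_D1
tips: euk_D1_marchantia, euk_D1_cycas, euk_D1_amborella, euk_D1_arabidopsis, euk_D1_populus
min: 0.475

name: diatoms_D1
tips: euk_D1_phaeodactylum, euk_D1_thalassiosira
min: 0.190

name: floridae_D1
tips: euk_D1_porphyra, euk_D1_phaeodactylum, euk_D1_thalassiosira, euk_D1_marchantia, euk_D1_cycas, euk_D1_amborella, euk_D1_arabidopsis, euk_D1_populus
min: 0.600

name: red_algae_D1
tips: euk_D1_cyanidium, euk_D1_galdieria, euk_D1_porphyra, euk_D1_phaeodactylum, euk_D1_thalassiosira, euk_D1_marchantia, euk_D1_cycas, euk_D1_amborella, euk_D1_arabidopsis, euk_D1_populus
min: 1.200

name: heterocystous_cyanobacteria
tips: G4_D1_nostoc, G4_D1_anabaena
min: 1.600

name: pleurocapsales
tips: G4_D1_pleurocapsa, G4_D1_chroococcidiopsis
min: 1.700

name: early_multicellular_cyanobacteria
tips: G4_D1_pseudanabaena, G4_D1_pleurocapsa, G4_D1_chroococcidiopsis, G4_D1_nostoc, G4_D1_anabaena, G4_D1_synechocystis, G4_D1_prochlorococcus, euk_D1_cyanidium, euk_D1_galdieria, euk_D1_porphyra, euk_D1_phaeodactylum, euk_D1_thalassiosira, euk_D1_marchantia, euk_D1_cycas, euk_D1_amborella, euk_D1_arabidopsis, euk_D1_populus
min: 1.900

name: crown_cyanobacteria_D1
tips: G4_D1_gloeobacter, G4_D1_pseudanabaena, G4_D1_pleurocapsa, G4_D1_chroococcidiopsis, G4_D1_nostoc, G4_D1_anabaena, G4_D1_synechocystis, G4_D1_prochlorococcus, euk_D1_cyanidium, euk_D1_galdieria, euk_D1_porphyra, euk_D1_phaeodactylum, euk_D1_thalassiosira, euk_D1_marchantia, euk_D1_cycas, euk_D1_amborella, euk_D1_arabidopsis, euk_D1_populus
min: 2.700

name: arabidopsis_populus_D2
tips: euk_D2_arabidopsis, euk_D2_populus
min: 0.082
max: 0.127

name: angiosperms_D2
tips: euk_D2_amborella, euk_D2_arabidopsis, euk_D2_populus
min: 0.124
max: 0.248

name: gymnosperms_D2
tips: euk_D2_cycas, euk_D2_amborella, euk_D2_arabidopsis, euk_D2_populus
min: 0.306
max: 0.366

name: land_plants_D2
tips: euk_D2_marchantia, euk_D2_cycas, euk_D2_amborella, euk_D2_arabidopsis, euk_D2_populus
min: 0.475

name: diatoms_D2
tips: euk_D2_phaeodactylum, euk_D2_thalassiosira
min: 0.190

name: floridae_D2
tips: euk_D2_porphyra, euk_D2_phaeodactylum, euk_D2_thalassiosira, euk_D2_marchantia, euk_D2_cycas, euk_D2_amborella, euk_D2_arabidopsis, euk_D2_populus
min: 0.600

name: red_algae_D2
tips: euk_D2_cyanidium, euk_D2_galdieria, euk_D2_porphyra, euk_D2_phaeodactylum, euk_D2_thalassiosira, euk_D2_marchantia, euk_D2_cycas, euk_D2_amborella, euk_D2_arabidopsis, euk_D2_populus
min: 1.200

name: crown_cyanobacteria_D2
tips: D2_gloeobacter, D2_pseudanabaena, D2_nostoc, D2_synechocystis, D2_thermosynechococcus, D2_prochlorococcus, euk_D2_cyanidium, euk_D2_galdieria, euk_D2_porphyra, euk_D2_phaeodactylum, euk_D2_thalassiosira, euk_D2_marchantia, euk_D2_cycas, euk_D2_amborella, euk_D2_arabidopsis, euk_D2_populus
min: 2.700
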