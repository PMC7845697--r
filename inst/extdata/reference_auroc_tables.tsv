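disease	pcnn_all	fc_all	fc_latent	fc_interaction	fc_chemical	logistic_regression	svm	xgboost	nc_verified	nc_verified_inferred
Carcinoma	0.774	0.684	0.767	0.702	0.711	0.673	0.715	0.752	0.767	0.813
Hypertension	0.970	0.962	0.955	0.882	0.777	0.827	0.846	0.878	0.912	0.935
Pain	0.943	0.776	0.840	0.815	0.611	0.761	0.793	0.822	0.871	0.903
Diabetes mellitus, type 2	0.850	0.765	0.824	0.564	0.616	0.714	0.766	0.810	0.793	0.822
Arthritis, rheumatoid	0.774	0.692	0.692	0.683	0.667	0.653	0.688	0.725	0.725	0.761
Urinary tract infections	0.985	0.983	0.948	0.986	0.944	0.903	0.934	0.952	0.846	0.910
Alzheimer's disease	0.864	0.757	0.859	0.588	0.810	0.772	0.817	0.831	0.827	0.841
Bacterial infections	0.948	0.926	0.880	0.717	0.865	0.851	0.826	0.916	0.879	0.927
Parkinson's disease	0.995	0.947	0.977	0.913	0.953	0.910	0.952	0.963	0.924	0.961
Heart failure	0.880	0.873	0.865	0.727	0.833	0.813	0.807	0.833	0.808	0.894
Sleep initiation and maintenance disorders	0.875	0.846	0.865	0.669	0.870	0.751	0.796	0.855	0.797	0.867
Skin diseases	0.774	0.789	0.759	0.587	0.653	0.725	0.740	0.781	0.718	0.785
Nausea	0.934	0.971	0.865	0.957	0.798	0.812	0.912	0.892	0.844	0.913
Myocardial infarction	0.964	0.798	0.800	0.975	0.766	0.836	0.881	0.893	0.902	0.947
Stroke	0.972	0.974	0.971	0.946	0.949	0.915	0.964	0.967	0.870	0.969
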